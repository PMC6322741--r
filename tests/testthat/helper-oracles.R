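# Independent oracle implementations, written against the stated rules and
# kept structurally different from the production code paths they check.

# --- IQD oracle: recursive, literal transcription of the tie-absorption
# rule. Partition the sorted values into m quantile bins (bin b closes at
# cumulative round(b * n / m)); on the first tie group that straddles a
# boundary, absorb it whole into the bin where its first member falls,
# fix all bins up to and including that one, and recurse on the rest.
iqd_oracle <- function(x, M) {
  n <- length(x)
  ord <- order(x, seq_len(n))
  v <- x[ord]
  lab_sorted <- integer(n)

  recurse <- function(from, first_bin, m) {
    len <- n - from + 1L
    if (len <= 0L || m <= 0L) return(invisible())
    if (m == 1L) {
      lab_sorted[from:n] <<- first_bin
      return(invisible())
    }
    bounds <- from - 1L + as.integer(round(seq_len(m) * len / m))
    # tentative assignment; find first straddling tie group
    for (b in seq_len(m - 1L)) {
      cut <- max(bounds[b], from + b - 1L)   # each bin keeps >= 1 point
      if (cut < n && v[cut + 1L] == v[cut]) {
        end <- cut
        while (end < n && v[end + 1L] == v[end]) end <- end + 1L
        # fix bins 1..b of this round, last one extended over the ties
        prev <- from - 1L
        for (bb in seq_len(b)) {
          stop_at <- if (bb == b) end else
            min(max(bounds[bb], from + bb - 1L), n)
          if (prev >= stop_at) next
          lab_sorted[(prev + 1L):stop_at] <<- first_bin + bb - 1L
          prev <- stop_at
        }
        recurse(end + 1L, first_bin + b, m - b)
        return(invisible())
      }
    }
    prev <- from - 1L
    for (bb in seq_len(m)) {
      stop_at <- if (bb == m) n else min(max(bounds[bb], from + bb - 1L), n)
      if (prev >= stop_at) next
      lab_sorted[(prev + 1L):stop_at] <<- first_bin + bb - 1L
      prev <- stop_at
    }
    invisible()
  }
  recurse(1L, 1L, as.integer(M))
  labels <- integer(n)
  labels[ord] <- lab_sorted
  used <- sort(unique(lab_sorted[lab_sorted > 0L]))
  match(labels, used)
}

# --- plug-in MI oracle: literal double sum over the empirical joint.
mi_brute <- function(tab) {
  N <- sum(tab)
  p <- tab / N
  pi <- rowSums(p); pj <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (pi[i] * pj[j]))
  }
  s
}

# --- DPI oracle: exhaustive enumeration of all node triples.
dpi_oracle <- function(net, tolerance) {
  nodes <- unique(c(net$regulator, net$substrate))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  w <- stats::setNames(net$mi, key(net$regulator, net$substrate))
  drop <- stats::setNames(logical(nrow(net)), key(net$regulator, net$substrate))
  cmb <- utils::combn(nodes, 3)
  for (t in seq_len(ncol(cmb))) {
    ks <- c(key(cmb[1, t], cmb[2, t]), key(cmb[1, t], cmb[3, t]),
            key(cmb[2, t], cmb[3, t]))
    if (!all(ks %in% names(w))) next
    wi <- w[ks]
    lo <- which.min(wi)
    if (wi[lo] < (1 - tolerance) * min(wi[-lo])) drop[ks[lo]] <- TRUE
  }
  net[!drop[key(net$regulator, net$substrate)], , drop = FALSE]
}

# --- GSEA running-sum oracle: literal walk over every rank position.
gsea_oracle <- function(scores, targets, weights) {
  N <- length(scores)
  o <- order(scores, decreasing = TRUE)
  z <- qnorm(rank(scores, ties.method = "average") / (N + 1))[o]
  nm <- names(scores)[o]
  hit <- nm %in% targets
  w <- numeric(N)
  w[hit] <- weights[match(nm[hit], targets)] * abs(z[hit])
  if (sum(w) <= 0) w[hit] <- 1
  k <- sum(hit)
  run <- 0; hi <- -Inf; lo <- Inf
  tot <- sum(w[hit])
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) w[i] / tot else -1 / (N - k)
    hi <- max(hi, run); lo <- min(lo, run)
  }
  if (hi >= -lo) hi else lo
}

# --- one-sided Fisher oracle: hypergeometric enumeration at fixed margins.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  x_obs <- tab[1, 1]
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  sum(probs[xs >= x_obs])
}

# --- simulation helpers shared across test files.
truth_peptide_edges <- function(sim) {
  m <- sim$matrix; tr <- sim$truth
  pmap <- split(m$peptides$id, m$peptides$gene)
  ed <- do.call(rbind, lapply(seq_len(nrow(tr$edges)), function(i)
    expand.grid(regulator = pmap[[tr$edges$regulator[i]]],
                substrate = pmap[[tr$edges$substrate[i]]],
                stringsAsFactors = FALSE)))
  ed$mi <- 1
  ed
}

shared_substrates <- function(truth, pair = 1L) {
  a <- truth$synergy_pairs$a[pair]; b <- truth$synergy_pairs$b[pair]
  ed <- truth$edges[truth$edges$type == "ts", ]
  intersect(ed$substrate[ed$regulator == a], ed$substrate[ed$regulator == b])
}

# small random weighted network over `n` nodes for DPI fuzzing
random_network <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  cmb <- utils::combn(nodes, 2)
  keep <- runif(ncol(cmb)) < p_edge
  data.frame(regulator = cmb[1, keep], substrate = cmb[2, keep],
             mi = round(runif(sum(keep), 0.05, 1), 3),
             stringsAsFactors = FALSE)
}
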