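#' Differential-phosphorylation signature of one sample
#'
#' Scores each peptide's spectral count in a test sample against the
#' normal-class reference group: `score = (x - mean(normals)) / s`, with
#' `s = max(sd(normals), s0)` and `s0` the median of the nonzero normal
#' standard deviations (a floor that keeps zero-variance peptides finite
#' without inflating well-measured ones). Higher score means
#' hyper-phosphorylated versus normal lung.
#'
#' @param m a [count_matrix()] with a class-tagged sample set containing at
#'   least two `normal` samples.
#' @param sample sample label to score.
#' @return object of class `phospho_signature`: list with `scores` (named
#'   numeric vector over peptides), `sample`, `n_normals`, `sd_floor`.
#' @export
compute_signature <- function(m, sample) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$classes))
    stop("sample classes are required (no class sidecar loaded)", call. = FALSE)
  if (!sample %in% colnames(m$counts))
    stop("unknown sample '", sample, "'", call. = FALSE)
  normals <- which(m$classes == "normal")
  if (length(normals) < 2)
    stop("need at least two normal-class samples", call. = FALSE)
  nm <- m$counts[, normals, drop = FALSE]
  mu <- rowMeans(nm)
  sdv <- apply(nm, 1L, stats::sd)
  nz <- sdv[sdv > 0]
  s0 <- if (length(nz)) stats::median(nz) else 1
  s <- pmax(sdv, s0)
  scores <- (m$counts[, sample] - mu) / s
  structure(list(scores = stats::setNames(scores, rownames(m$counts)),
                 sample = sample, n_normals = length(normals), sd_floor = s0),
            class = "phospho_signature")
}

#' @export
print.phospho_signature <- function(x, ...) {
  cat("Phospho signature for sample '", x$sample, "' (",
      length(x$scores), " peptides vs ", x$n_normals, " normals)\n", sep = "")
  invisible(x)
}

#' Correlation-filtered substrate sets (signalons)
#'
#' For each regulator in the network, retains the substrates whose Spearman
#' correlation with the regulator's counts is significant at `alpha` after
#' Bonferroni correction over that regulator's candidate substrates. Each
#' retained target carries the correlation sign and an `|rho|` weight.
#' Negative-sign targets are kept in the object but excluded from
#' enrichment (kinases essentially only induce positive phospho-state
#' coupling, so the enrichment is single-tail).
#'
#' @param net edge data.frame or `paracne` fit.
#' @param m the [count_matrix()].
#' @param alpha significance level (Bonferroni-corrected per regulator).
#' @return named list of signalons; each a list with `regulator`,
#'   `targets` (data.frame `substrate`, `sign`, `weight`), `n_candidates`.
#'   Empty signalons are kept and flagged (`empty = TRUE`).
#' @export
build_signalons <- function(net, m, alpha = 0.05) {
  edges <- if (inherits(net, "paracne")) net$network else as.data.frame(net)
  stopifnot(inherits(m, "count_matrix"))
  miss <- setdiff(unique(c(edges$regulator, edges$substrate)), m$peptides$id)
  if (length(miss))
    stop("peptide '", miss[1L], "' not present in the matrix", call. = FALSE)
  if (is.null(edges$rho) || is.null(edges$rho_p))
    edges <- annotate_spearman(edges, m)
  out <- list()
  for (r in unique(edges$regulator)) {
    sub <- edges[edges$regulator == r, , drop = FALSE]
    n_cand <- nrow(sub)
    ok <- isTRUE_vec(sub$rho_defined) & (sub$rho_p * n_cand <= alpha)
    tg <- data.frame(substrate = sub$substrate[ok],
                     sign = sign(sub$rho[ok]),
                     weight = abs(sub$rho[ok]),
                     stringsAsFactors = FALSE)
    out[[r]] <- list(regulator = r, targets = tg, n_candidates = n_cand,
                     empty = !nrow(tg))
  }
  out
}

# Normal quantiles of the score ranks (monotone; preserves order and sign
# structure around the median while bounding extremes).
rank_normalize <- function(scores) {
  n <- length(scores)
  stats::qnorm(rank(scores, ties.method = "average") / (n + 1))
}

# Enrichment score of a weighted target set in a ranked signature.
# Weighted Kolmogorov-Smirnov running sum: the signature is ranked by
# signed score (descending); hits advance by weight * |score|, misses
# retreat by 1/(N - n_targets); ES is the extreme deviation (signed).
# `positions` are ranks of the targets in the sorted signature,
# `hitw` their weights * |score at that rank|. O(n_targets).
.gsea_es <- function(positions, hitw, N) {
  k <- length(positions)
  if (!k) return(NA_real_)
  o <- order(positions)
  p <- positions[o]
  w <- hitw[o]
  tot <- sum(w)
  if (tot <= 0) { w <- rep(1, k); tot <- k }
  cumw <- cumsum(w) / tot
  miss_unit <- 1 / (N - k)
  # deviation just after each hit, and just before each hit
  after <- cumw - (p - seq_len(k)) * miss_unit
  before <- c(0, cumw[-k]) - (p - 1 - (seq_len(k) - 1)) * miss_unit
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Single-tail enrichment of a signalon in a signature
#'
#' Computes a weighted Kolmogorov-Smirnov enrichment score (ES) of the
#' signalon's positive-sign targets in the signature ranked by signed
#' score, then standardizes against a peptide-label permutation null of
#' matched set size: `NES = (ES - mean(null)) / sd(null)`, with an
#' empirical two-sided p-value. Positive NES means the kinase's substrates
#' are hyper-phosphorylated in the sample; negative means hypo.
#'
#' Hit weights are `|rho| * |z|^1` where `z` is the rank-normalized
#' signature (normal quantiles of the score ranks). Rank normalization is
#' monotone — the ranking itself is untouched — but bounds the weights, so
#' a single extreme peptide (common in majority-zero count signatures,
#' where the reference variance is floored) cannot dominate both the
#' observed and the null running sums.
#'
#' @param sig a [compute_signature()] result (or named score vector).
#' @param s a signalon (element of [build_signalons()]).
#' @param n_perm permutations for the null.
#' @param seed RNG seed.
#' @return list with `es`, `nes`, `p`, `n_targets`; when no usable target
#'   exists, a flagged null result (`empty = TRUE`, `nes = NA`).
#' @export
enrichment_nes <- function(sig, s, n_perm = 1000, seed = 1) {
  scores <- if (inherits(sig, "phospho_signature")) sig$scores else sig
  tg <- s$targets[s$targets$sign > 0, , drop = FALSE]
  tg <- tg[tg$substrate %in% names(scores), , drop = FALSE]
  if (!nrow(tg))
    return(list(es = NA_real_, nes = NA_real_, p = NA_real_,
                n_targets = 0L, empty = TRUE))
  N <- length(scores)
  o <- order(scores, decreasing = TRUE)
  ranked <- rank_normalize(scores)[o]
  rank_of <- stats::setNames(seq_len(N), names(scores)[o])
  pos <- unname(rank_of[tg$substrate])
  hitw <- tg$weight * abs(ranked[pos])
  es <- .gsea_es(pos, hitw, N)
  k <- nrow(tg)
  local_rng(seed)
  null_es <- numeric(n_perm)
  absr <- abs(ranked)
  for (b in seq_len(n_perm)) {
    rp <- sample.int(N, k)
    null_es[b] <- .gsea_es(rp, tg$weight * absr[rp], N)
  }
  mu <- mean(null_es); sdv <- stats::sd(null_es)
  nes <- (es - mu) / sdv
  null_z <- (null_es - mu) / sdv
  p <- (1 + sum(abs(null_z) >= abs(nes))) / (1 + n_perm)
  list(es = es, nes = nes, p = p, n_targets = k, empty = FALSE)
}

#' Synergy of a kinase pair
#'
#' Scores the enrichment of the substrates *shared* by two signalons
#' against a null of equally sized random subsets of the *unique* (union
#' minus intersection) substrates. A significantly stronger shared-set
#' enrichment indicates that the sample's phospho-state depends jointly on
#' both kinases.
#'
#' @param sig signature.
#' @param sA,sB signalons.
#' @param n_perm null draws.
#' @param seed RNG seed.
#' @return list with `es_shared`, `nes`, `p` (one-sided: fraction of null
#'   >= observed), `n_shared`; flagged null result when the intersection
#'   (or the unique pool) is empty.
#' @export
pair_synergy <- function(sig, sA, sB, n_perm = 1000, seed = 1) {
  scores <- if (inherits(sig, "phospho_signature")) sig$scores else sig
  pos_targets <- function(s) {
    tg <- s$targets[s$targets$sign > 0, , drop = FALSE]
    tg[tg$substrate %in% names(scores), , drop = FALSE]
  }
  ta <- pos_targets(sA); tb <- pos_targets(sB)
  shared <- intersect(ta$substrate, tb$substrate)
  uniq <- setdiff(union(ta$substrate, tb$substrate), shared)
  if (!length(shared) || length(uniq) < length(shared))
    return(list(es_shared = NA_real_, nes = NA_real_, p = NA_real_,
                n_shared = length(shared), empty = TRUE))
  allw <- rbind(ta, tb)
  w_of <- tapply(allw$weight, allw$substrate, max)
  N <- length(scores)
  o <- order(scores, decreasing = TRUE)
  ranked <- rank_normalize(scores)[o]
  rank_of <- stats::setNames(seq_len(N), names(scores)[o])
  es_of <- function(set) {
    pos <- unname(rank_of[set])
    .gsea_es(pos, unname(w_of[set]) * abs(ranked[pos]), N)
  }
  es <- es_of(shared)
  k <- length(shared)
  local_rng(seed)
  null_es <- vapply(seq_len(n_perm), function(b) es_of(sample(uniq, k)), 0)
  mu <- mean(null_es); sdv <- stats::sd(null_es)
  p <- (1 + sum(null_es >= es)) / (1 + n_perm)
  list(es_shared = es, nes = if (sdv > 0) (es - mu) / sdv else NA_real_,
       p = p, n_shared = k, empty = FALSE)
}

#' Master-regulator analysis of phosphoproteomic profiles (pVIPER)
#'
#' For each requested sample, computes the differential-phosphorylation
#' signature against the normal reference group and the single-tail NES of
#' every regulator's signalon; peptide-level NES values of the same kinase
#' gene are combined by Stouffer's method (equal weights), and per-sample
#' p-values are Benjamini-Hochberg adjusted. Optionally scores designated
#' (or all co-significant) kinase pairs for synergy.
#'
#' @param m a class-tagged [count_matrix()].
#' @param net a `paracne` fit or annotated edge data.frame.
#' @param samples sample labels to analyze; defaults to all non-normal
#'   samples.
#' @param pairs `NULL` (no synergy), `"auto"` (all pairs of per-sample
#'   significant kinases), or a two-column matrix/data.frame of regulator
#'   peptide ids.
#' @param alpha significance level for the per-sample BH cut.
#' @param n_perm permutations per enrichment.
#' @param seed RNG seed.
#' @return object of class `pviper`: list with `peptide` (long data.frame:
#'   sample, regulator peptide, gene, nes, p), `protein` (sample, gene,
#'   nes, p, q, significant), `pairs` (synergy results, possibly empty),
#'   `signalons`, `params`, `call`.
#' @export
pviper <- function(m, net, samples = NULL, pairs = NULL, alpha = 0.05,
                   n_perm = 1000, seed = 1) {
  cl <- match.call()
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$classes))
    stop("sample classes are required for pVIPER", call. = FALSE)
  if (is.null(samples))
    samples <- colnames(m$counts)[m$classes != "normal"]
  signalons <- build_signalons(net, m)
  usable <- names(signalons)[!vapply(signalons, `[[`, TRUE, "empty")]
  pep_rows <- list()
  pair_rows <- list()
  for (smp in samples) {
    sig <- compute_signature(m, smp)
    for (r in usable) {
      en <- enrichment_nes(sig, signalons[[r]], n_perm = n_perm,
                           seed = seed + which(samples == smp))
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        sample = smp, regulator = r,
        gene = parse_peptide_id(r, "dollar")$gene,
        nes = en$nes, p = en$p, n_targets = en$n_targets,
        stringsAsFactors = FALSE)
    }
  }
  peptide <- do.call(rbind, pep_rows)

  # Stouffer combination per (sample, gene). Peptide evidence enters as the
  # signed normal transform of its own calibrated permutation p-value
  # (sign from NES), which is comparable across regulators with different
  # target-set sizes and null widths; raw NES is kept for direction and as
  # the ranking tie-break.
  prot_rows <- list()
  for (smp in unique(peptide$sample)) {
    ps <- peptide[peptide$sample == smp & is.finite(peptide$nes), , drop = FALSE]
    if (!nrow(ps)) next
    zp <- sign(ps$nes) * stats::qnorm(1 - pmin(ps$p, 1 - 1e-12) / 2)
    for (g in unique(ps$gene)) {
      i <- ps$gene == g
      zc <- sum(zp[i]) / sqrt(sum(i))
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        sample = smp, gene = g, nes = sum(ps$nes[i]) / sqrt(sum(i)),
        z = zc, p = 2 * stats::pnorm(-abs(zc)), n_peptides = sum(i),
        stringsAsFactors = FALSE)
    }
  }
  protein <- do.call(rbind, prot_rows)
  if (!is.null(protein) && nrow(protein)) {
    protein$q <- NA_real_
    for (smp in unique(protein$sample)) {
      i <- protein$sample == smp
      protein$q[i] <- stats::p.adjust(protein$p[i], method = "BH")
    }
    protein$significant <- protein$q <= alpha
    protein <- protein[order(protein$sample, protein$p, -abs(protein$nes)), ,
                       drop = FALSE]
  }

  if (!is.null(pairs)) {
    pair_set <- if (identical(pairs, "auto")) {
      do.call(rbind, lapply(unique(peptide$sample), function(smp) {
        sg <- protein[protein$sample == smp & protein$significant, , drop = FALSE]
        regs <- usable[vapply(usable, function(r)
          parse_peptide_id(r, "dollar")$gene %in% sg$gene, TRUE)]
        if (length(regs) < 2) return(NULL)
        cmb <- utils::combn(regs, 2)
        data.frame(sample = smp, a = cmb[1, ], b = cmb[2, ],
                   stringsAsFactors = FALSE)
      }))
    } else {
      pr <- as.data.frame(pairs, stringsAsFactors = FALSE)
      names(pr)[1:2] <- c("a", "b")
      merge(data.frame(sample = samples), pr)
    }
    if (!is.null(pair_set) && nrow(pair_set)) {
      for (i in seq_len(nrow(pair_set))) {
        smp <- pair_set$sample[i]
        sig <- compute_signature(m, smp)
        sy <- pair_synergy(sig, signalons[[pair_set$a[i]]],
                           signalons[[pair_set$b[i]]],
                           n_perm = n_perm, seed = seed + i)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          sample = smp, a = pair_set$a[i], b = pair_set$b[i],
          nes = sy$nes, p = sy$p, n_shared = sy$n_shared,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs_df <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(sample = character(), a = character(), b = character(),
               nes = numeric(), p = numeric(), n_shared = integer())

  structure(list(peptide = peptide, protein = protein, pairs = pairs_df,
                 signalons = signalons,
                 params = list(alpha = alpha, n_perm = n_perm, seed = seed),
                 call = cl),
            class = "pviper")
}

#' @export
print.pviper <- function(x, ...) {
  cat("pVIPER master-regulator analysis\n")
  cat("  ", length(unique(x$protein$sample)), " samples x ",
      length(unique(x$protein$gene)), " kinases\n", sep = "")
  nsig <- sum(x$protein$significant, na.rm = TRUE)
  cat("  significant (sample, kinase) calls:", nsig, "\n")
  if (nrow(x$pairs))
    cat("  synergistic pairs tested:", nrow(x$pairs),
        " significant:", sum(x$pairs$p <= x$params$alpha, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
summary.pviper <- function(object, ...) {
  per_sample <- tapply(object$protein$significant, object$protein$sample, sum)
  s <- list(n_samples = length(per_sample),
            mr_per_sample = per_sample,
            top = do.call(rbind, lapply(split(object$protein,
                                              object$protein$sample),
                                        function(d) d[1L, ])))
  class(s) <- "summary.pviper"
  s
}

#' @export
print.summary.pviper <- function(x, ...) {
  cat("Significant master regulators per sample:\n")
  print(x$mr_per_sample)
  cat("Top regulator per sample:\n")
  print(x$top[, c("sample", "gene", "nes", "q")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.pviper <- function(x, ...) {
  d <- x$protein
  tab <- tapply(d$nes, list(d$gene, d$sample), mean)
  tab[is.na(tab)] <- 0
  graphics::image(t(tab), axes = FALSE, col = grDevices::hcl.colors(25, "Blue-Red"),
                  main = "pVIPER NES (kinase x sample)")
  graphics::axis(2, at = seq(0, 1, length.out = nrow(tab)),
                 labels = rownames(tab), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Phosphosite-level sensitivity rule for an inhibitor combination
#'
#' Classifies samples by which phosphosites drive their predicted kinase
#' dependencies, mirroring the observation that combination sensitivity
#' tracks specific site pairs (EGFR site 1197 with MET site 1003 by
#' default): `combo_sensitive` when the two named sites form a significant
#' synergistic pair; `single_agent` when site A is individually significant
#' (or synergistic with a partner other than site B) without the A/B pair;
#' `insensitive` otherwise.
#'
#' @param fit a `pviper` fit with peptide-level results and pairs.
#' @param siteA,siteB canonical peptide ids of the two sites.
#' @param alpha significance cut.
#' @return data.frame: `sample`, `label`; attribute `flagged` is TRUE when
#'   a named site is absent from the analyzed network.
#' @export
phosphosite_rule_classifier <- function(fit, siteA = "EGFR$1197",
                                        siteB = "MET$1003", alpha = 0.05) {
  stopifnot(inherits(fit, "pviper"))
  siteA <- format_peptide_id(parse_peptide_id(siteA, detect_dialect(siteA)), "dollar")
  siteB <- format_peptide_id(parse_peptide_id(siteB, detect_dialect(siteB)), "dollar")
  known <- unique(fit$peptide$regulator)
  flagged <- !(siteA %in% known) || !(siteB %in% known)
  samples <- unique(fit$peptide$sample)
  lab <- character(length(samples))
  for (i in seq_along(samples)) {
    smp <- samples[i]
    pp <- fit$pairs[fit$pairs$sample == smp, , drop = FALSE]
    ab <- pp[(pp$a == siteA & pp$b == siteB) |
             (pp$a == siteB & pp$b == siteA), , drop = FALSE]
    a_other <- pp[(pp$a == siteA & pp$b != siteB) |
                  (pp$b == siteA & pp$a != siteB), , drop = FALSE]
    pe <- fit$peptide[fit$peptide$sample == smp &
                      fit$peptide$regulator == siteA, , drop = FALSE]
    a_alone <- nrow(pe) && any(is.finite(pe$nes) & pe$nes > 0 & pe$p <= alpha)
    if (nrow(ab) && any(ab$p <= alpha, na.rm = TRUE)) {
      lab[i] <- "combo_sensitive"
    } else if ((nrow(a_other) && any(a_other$p <= alpha, na.rm = TRUE)) ||
               a_alone) {
      lab[i] <- "single_agent"
    } else {
      lab[i] <- "insensitive"
    }
  }
  out <- data.frame(sample = samples, label = lab, stringsAsFactors = FALSE)
  attr(out, "flagged") <- flagged
  out
}
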