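#' Candidate kinase-substrate edges by mutual information
#'
#' Scores every (kinase peptide, other peptide) pair by plug-in MI on
#' IQD-discretized rows and keeps pairs passing the significance screen.
#' Self-pairs (a peptide with itself) are excluded; distinct phosphosites
#' of the same gene are eligible, so cis-autophosphorylation edges can be
#' inferred. Kinase-kinase pairs are scored once (unordered).
#'
#' Significance is tested at level `alpha` Bonferroni-corrected over the
#' number of tested pairs. The default (`sig_method = "chisq"`) uses the
#' asymptotic chi-square law of the G statistic `2 N MI` with
#' `(Mx_eff - 1)(My_eff - 1)` degrees of freedom per pair, which conditions
#' the null — including the plug-in estimator's `df / 2N` bias — on each
#' pair's effective bin counts. `"permutation"` instead estimates one
#' pooled permutation null over randomly re-paired rows and extrapolates
#' its Bonferroni quantile through an exponential tail fit; because the
#' pool mixes pairs of very different effective bin counts it is
#' conservative for sparse rows.
#'
#' @param m a [count_matrix()].
#' @param kinases character vector of tyrosine-kinase gene symbols.
#' @param M number of IQD bins (default 10).
#' @param alpha significance level before Bonferroni correction.
#' @param sig_method `"chisq"` (default) or `"permutation"`.
#' @param n_null pooled null draws for the permutation calibration.
#' @param seed RNG seed.
#' @param bins optional precomputed [discretize_matrix()] result.
#' @return data.frame of edges: `regulator`, `substrate` (canonical peptide
#'   ids), `mi`. Regulator is always a kinase peptide; for kinase-kinase
#'   edges the row-order-first peptide is the regulator column.
#' @export
infer_candidate_edges <- function(m, kinases, M = 10, alpha = 0.05,
                                  sig_method = c("chisq", "permutation"),
                                  n_null = 3000, seed = 1, bins = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  sig_method <- match.arg(sig_method)
  kinases <- normalize_gene(kinases)
  if (M < 2) stop("'M' must be >= 2 for edge inference", call. = FALSE)
  is_kin <- m$peptides$gene %in% kinases
  if (!any(is_kin))
    stop("no kinase peptide found in the matrix", call. = FALSE)
  if (is.null(bins)) bins <- discretize_matrix(m, M)
  ids <- m$peptides$id
  kin_idx <- which(is_kin)
  N <- ncol(m$counts)

  # enumerate tested pairs: kinase x everything, unordered among kinases
  reg <- integer(0); tgt <- integer(0)
  for (i in kin_idx) {
    js <- setdiff(seq_along(ids), i)
    js <- js[!(is_kin[js] & js < i)]   # kinase pairs only once (i < j)
    reg <- c(reg, rep.int(i, length(js)))
    tgt <- c(tgt, js)
  }
  n_pairs <- length(reg)

  mi <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    mi[k] <- mi_from_labels(bins[[reg[k]]]$labels, bins[[tgt[k]]]$labels)
  }

  if (sig_method == "permutation") {
    null_fit <- fit_mi_null(bins[kin_idx], bins, n_null = n_null, seed = seed)
    thr <- null_fit$threshold(alpha / n_pairs)
    keep <- mi > thr
  } else {
    df_pair <- vapply(seq_len(n_pairs), function(k)
      (bins[[reg[k]]]$M_effective - 1) * (bins[[tgt[k]]]$M_effective - 1), 0)
    p <- ifelse(df_pair > 0,
                stats::pchisq(2 * N * mi, df = df_pair, lower.tail = FALSE), 1)
    keep <- p <= alpha / n_pairs
  }

  data.frame(regulator = ids[reg[keep]], substrate = ids[tgt[keep]],
             mi = mi[keep], stringsAsFactors = FALSE)
}

#' Data processing inequality pruning
#'
#' For every triangle of network edges (TK1-TK2, TK1-S, TK2-S) the weakest
#' edge is the candidate indirect interaction: it is removed when its MI is
#' below `(1 - tolerance)` times the smaller of the other two. All
#' triangles are scanned first and removals applied simultaneously, so the
#' result does not depend on scan order. Only triangles whose two "path"
#' edges involve kinase regulators exist in this network (substrate pairs
#' are never scored), so every network triangle is tested.
#'
#' @param net edge data.frame (`regulator`, `substrate`, `mi`).
#' @param tolerance real in `[0, 1)`; 0 is the strict DPI.
#' @return the pruned edge data.frame.
#' @export
apply_dpi <- function(net, tolerance = 0) {
  if (tolerance < 0 || tolerance >= 1)
    stop("'tolerance' must be in [0, 1)", call. = FALSE)
  if (!nrow(net)) return(net)
  nodes <- unique(c(net$regulator, net$substrate))
  n <- length(nodes)
  a <- match(net$regulator, nodes)
  b <- match(net$substrate, nodes)
  W <- matrix(0, n, n)
  W[cbind(a, b)] <- net$mi
  W[cbind(b, a)] <- net$mi
  E <- matrix(0L, n, n)
  E[cbind(a, b)] <- seq_len(nrow(net))
  E[cbind(b, a)] <- seq_len(nrow(net))
  drop <- logical(nrow(net))
  # scan triangles once through each edge's common neighbors (i < j)
  for (e in seq_len(nrow(net))) {
    i <- a[e]; j <- b[e]
    ks <- which(W[i, ] > 0 & W[j, ] > 0)
    for (k in ks) {
      if (k == i || k == j) next
      w <- c(W[i, j], W[i, k], W[j, k])
      eid <- c(E[i, j], E[i, k], E[j, k])
      lo <- which.min(w)
      others <- w[-lo]
      if (w[lo] < (1 - tolerance) * min(others)) drop[eid[lo]] <- TRUE
    }
  }
  net[!drop, , drop = FALSE]
}

#' Bootstrap inference and Poisson consolidation
#'
#' Runs candidate-edge inference plus DPI on `B` bootstrap resamples of the
#' samples (columns, with replacement) and consolidates: an edge enters the
#' final network when its support count (number of bootstrap networks
#' containing it) is significantly larger than chance under a Poisson model
#' whose mean is the expected support of a random tested pair (total
#' support over tested pairs), Bonferroni-corrected at
#' 0.05 across distinct edges. The final MI is the mean over supporting
#' bootstraps. With `consolidate = "majority"` an edge is kept when its
#' support exceeds `B/2`.
#'
#' With the permutation screen, the MI significance threshold is calibrated
#' once on the full matrix and reused across bootstraps; the chi-square
#' screen (default) is recomputed per bootstrap from each pair's realized
#' bins.
#'
#' @inheritParams infer_candidate_edges
#' @param tolerance DPI tolerance.
#' @param B number of bootstraps (>= 2).
#' @param consolidate `"poisson"` or `"majority"`.
#' @return edge data.frame: `regulator`, `substrate`, `mi` (mean over
#'   supporting bootstraps), `support`.
#' @export
bootstrap_consolidate <- function(m, kinases, M = 10, alpha = 0.05,
                                  tolerance = 0, B = 100, seed = 1,
                                  sig_method = c("chisq", "permutation"),
                                  n_null = 3000,
                                  consolidate = c("poisson", "majority")) {
  stopifnot(inherits(m, "count_matrix"))
  sig_method <- match.arg(sig_method)
  consolidate <- match.arg(consolidate)
  if (B < 2) stop("'B' must be >= 2", call. = FALSE)
  local_rng(seed)
  N <- ncol(m$counts)

  # fixed MI threshold from the full matrix (permutation method only)
  if (sig_method == "permutation") {
    bins_full <- discretize_matrix(m, M)
    kin_idx <- which(m$peptides$gene %in% normalize_gene(kinases))
    if (!length(kin_idx)) stop("no kinase peptide found in the matrix", call. = FALSE)
    null_fit <- fit_mi_null(bins_full[kin_idx], bins_full, n_null = n_null,
                            seed = seed)
  }

  support <- new.env(parent = emptyenv())
  mi_sum <- new.env(parent = emptyenv())
  for (b in seq_len(B)) {
    cols <- sample.int(N, N, replace = TRUE)
    mb <- m
    mb$counts <- m$counts[, cols, drop = FALSE]
    colnames(mb$counts) <- paste0("b", seq_len(N))
    if (!is.null(mb$classes)) {
      mb$classes <- mb$classes[cols]
      names(mb$classes) <- colnames(mb$counts)
    }
    bins_b <- discretize_matrix(mb, M)
    if (sig_method == "permutation") {
      net_b <- infer_candidate_edges_thresholded(mb, kinases, bins_b,
                                                 null_fit, alpha)
    } else {
      net_b <- infer_candidate_edges(mb, kinases, M = M, alpha = alpha,
                                     sig_method = "chisq", bins = bins_b)
    }
    net_b <- apply_dpi(net_b, tolerance = tolerance)
    if (nrow(net_b)) {
      keys <- paste(net_b$regulator, net_b$substrate, sep = "\r")
      for (k in seq_along(keys)) {
        key <- keys[k]
        support[[key]] <- (if (is.null(support[[key]])) 0L else support[[key]]) + 1L
        mi_sum[[key]] <- (if (is.null(mi_sum[[key]])) 0 else mi_sum[[key]]) +
          net_b$mi[k]
      }
    }
  }

  keys <- ls(support)
  if (!length(keys))
    return(data.frame(regulator = character(), substrate = character(),
                      mi = numeric(), support = integer()))
  supp <- vapply(keys, function(k) support[[k]], 0L)
  mis <- vapply(keys, function(k) mi_sum[[k]], 0) / supp
  if (consolidate == "poisson") {
    is_kin <- m$peptides$gene %in% normalize_gene(kinases)
    nk <- sum(is_kin); np <- nrow(m$counts)
    n_pairs <- nk * (np - 1) - choose(nk, 2)   # tested pair universe
    lambda <- sum(supp) / n_pairs
    pp <- stats::ppois(supp - 1L, lambda, lower.tail = FALSE)
    keep <- pp < 0.05 / length(supp)
  } else {
    keep <- supp > B / 2
  }
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  out <- data.frame(
    regulator = vapply(parts, `[[`, "", 1L),
    substrate = vapply(parts, `[[`, "", 2L),
    mi = unname(mis[keep]), support = unname(supp[keep]),
    stringsAsFactors = FALSE)
  out[order(-out$mi), , drop = FALSE]
}

# Candidate inference against a precomputed MI threshold (bootstrap path).
infer_candidate_edges_thresholded <- function(m, kinases, bins, null_fit,
                                              alpha) {
  kinases <- normalize_gene(kinases)
  is_kin <- m$peptides$gene %in% kinases
  ids <- m$peptides$id
  kin_idx <- which(is_kin)
  reg <- integer(0); tgt <- integer(0)
  for (i in kin_idx) {
    js <- setdiff(seq_along(ids), i)
    js <- js[!(is_kin[js] & js < i)]
    reg <- c(reg, rep.int(i, length(js)))
    tgt <- c(tgt, js)
  }
  thr <- null_fit$threshold(alpha / length(reg))
  mi <- numeric(length(reg))
  for (k in seq_along(reg))
    mi[k] <- mi_from_labels(bins[[reg[k]]]$labels, bins[[tgt[k]]]$labels)
  keep <- mi > thr
  data.frame(regulator = ids[reg[keep]], substrate = ids[tgt[keep]],
             mi = mi[keep], stringsAsFactors = FALSE)
}

#' Spearman sign annotation of network edges
#'
#' Attaches per-edge Spearman correlation `rho` and its p-value, computed on
#' the raw count rows. Edges whose substrate (or regulator) row is constant
#' have undefined rho; they are flagged (`rho_defined = FALSE`) and
#' excluded from the negative-fraction denominator reported by
#' [negative_rho_report()].
#'
#' @param net edge data.frame.
#' @param m the [count_matrix()] the network was inferred from.
#' @return `net` with columns `rho`, `rho_p`, `rho_defined` added.
#' @export
annotate_spearman <- function(net, m) {
  stopifnot(inherits(m, "count_matrix"))
  if (!nrow(net)) {
    net$rho <- numeric(0); net$rho_p <- numeric(0); net$rho_defined <- logical(0)
    return(net)
  }
  miss <- setdiff(unique(c(net$regulator, net$substrate)), m$peptides$id)
  if (length(miss))
    stop("peptide '", miss[1L], "' not present in the matrix", call. = FALSE)
  rho <- rho_p <- rep(NA_real_, nrow(net))
  for (e in seq_len(nrow(net))) {
    x <- m$counts[net$regulator[e], ]
    y <- m$counts[net$substrate[e], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    rho[e] <- unname(ct$estimate)
    rho_p[e] <- ct$p.value
  }
  net$rho <- rho
  net$rho_p <- rho_p
  net$rho_defined <- !is.na(rho)
  net
}

#' Report the negatively correlated edge fraction
#'
#' Counts edges with `rho < 0` at two-sided `rho_p <= p_cut` among edges
#' with defined rho.
#'
#' @param net an annotated edge data.frame (see [annotate_spearman()]) or a
#'   `paracne` fit.
#' @param p_cut significance cut for calling an edge's sign (uncorrected).
#' @return list with `n_negative`, `n_edges` (defined-rho denominator),
#'   `fraction`, and `fraction_positive` among sign-significant edges.
#' @export
negative_rho_report <- function(net, p_cut = 0.05) {
  edges <- if (inherits(net, "paracne")) net$network else net
  def <- edges[isTRUE_vec(edges$rho_defined), , drop = FALSE]
  neg <- sum(def$rho < 0 & def$rho_p <= p_cut, na.rm = TRUE)
  sig <- sum(def$rho_p <= p_cut, na.rm = TRUE)
  list(n_negative = neg, n_edges = nrow(def),
       fraction = if (nrow(def)) neg / nrow(def) else NA_real_,
       fraction_positive = if (sig) 1 - neg / sig else NA_real_)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Aggregate a peptide-level network to the protein level
#'
#' One edge per (kinase gene, substrate gene) pair carrying the maximum MI
#' over the contributing peptide-level edges. Idempotent on networks that
#' are already protein-unique.
#'
#' @param net peptide-level edge data.frame or `paracne` fit.
#' @return data.frame: `regulator`, `substrate` (gene symbols), `mi`
#'   (maximum), `n_peptide_edges`.
#' @export
aggregate_to_protein <- function(net) {
  edges <- if (inherits(net, "paracne")) net$network else as.data.frame(net)
  if (!nrow(edges)) stop("cannot aggregate an empty network", call. = FALSE)
  rg <- vapply(edges$regulator, function(id) parse_peptide_id(id, "dollar")$gene, "")
  sg <- vapply(edges$substrate, function(id) parse_peptide_id(id, "dollar")$gene, "")
  key <- paste(rg, sg, sep = "\r")
  agg_mi <- tapply(edges$mi, key, max)
  agg_n <- tapply(edges$mi, key, length)
  parts <- strsplit(names(agg_mi), "\r", fixed = TRUE)
  out <- data.frame(
    regulator = vapply(parts, `[[`, "", 1L),
    substrate = vapply(parts, `[[`, "", 2L),
    mi = unname(as.numeric(agg_mi)),
    n_peptide_edges = unname(as.integer(agg_n)),
    stringsAsFactors = FALSE)
  out[order(-out$mi), , drop = FALSE]
}

#' Test for enrichment of kinase-kinase edges
#'
#' Hypergeometric right-tail probability of observing at least the seen
#' number of TK->TK edges, treating the network's edges as draws from the
#' urn of all possible (kinase gene, target gene) pairs over the matrix's
#' gene universe; pairs whose target is a kinase are the white balls.
#'
#' @param pn protein-level network (see [aggregate_to_protein()]).
#' @param kinases kinase gene symbols.
#' @param universe optional character vector of all candidate target genes;
#'   defaults to all genes appearing in `pn` plus `kinases`.
#' @return list with `n_tk_tk`, `n_edges`, `p`.
#' @export
tk_tk_bias_test <- function(pn, kinases, universe = NULL) {
  if (!nrow(pn)) stop("empty protein network", call. = FALSE)
  kinases <- normalize_gene(kinases)
  if (is.null(universe)) universe <- unique(c(pn$regulator, pn$substrate, kinases))
  universe <- unique(universe)
  n_tk <- sum(universe %in% kinases)
  n_gene <- length(universe)
  obs <- sum(pn$substrate %in% kinases)
  white <- n_tk * n_tk                    # (TK regulator, TK target) pairs
  black <- n_tk * (n_gene - n_tk)
  p <- stats::phyper(obs - 1L, m = white, n = black, k = nrow(pn),
                     lower.tail = FALSE)
  list(n_tk_tk = obs, n_edges = nrow(pn), p = p)
}

#' Fit a kinase-substrate signaling network from spectral counts
#'
#' The top-level fitting function: bootstrap mutual-information inference
#' with iterative quantile discretization, DPI pruning and Poisson
#' consolidation, followed by Spearman sign annotation and protein-level
#' aggregation.
#'
#' @inheritParams bootstrap_consolidate
#' @return an object of class `paracne`: list with `network` (annotated
#'   peptide-level edges), `protein` (protein-level aggregation),
#'   `kinases`, `tk_tk` (bias test), `params`, and `call`. Methods:
#'   `print`, `summary`, `plot`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_tk = 3, n_substrates = 15,
#'   edges_per_tk = 4,
#'   n_samples = c(tumor = 30, cell_line = 10, normal = 10), seed = 7))
#' fit <- paracne(sim$matrix, sim$kinases, B = 5)
#' fit
#' @export
paracne <- function(m, kinases, M = 10, alpha = 0.05, tolerance = 0,
                    B = 100, seed = 1,
                    sig_method = c("chisq", "permutation"), n_null = 3000,
                    consolidate = c("poisson", "majority")) {
  cl <- match.call()
  sig_method <- match.arg(sig_method)
  consolidate <- match.arg(consolidate)
  kinases <- normalize_gene(kinases)
  net <- bootstrap_consolidate(m, kinases, M = M, alpha = alpha,
                               tolerance = tolerance, B = B, seed = seed,
                               sig_method = sig_method, n_null = n_null,
                               consolidate = consolidate)
  net <- annotate_spearman(net, m)
  protein <- if (nrow(net)) aggregate_to_protein(net) else
    data.frame(regulator = character(), substrate = character(),
               mi = numeric(), n_peptide_edges = integer())
  tk_tk <- if (nrow(protein)) tk_tk_bias_test(protein, kinases,
                                              universe = unique(m$peptides$gene))
           else NULL
  structure(list(network = net, protein = protein, kinases = kinases,
                 tk_tk = tk_tk,
                 params = list(M = M, alpha = alpha, tolerance = tolerance,
                               B = B, seed = seed, sig_method = sig_method,
                               consolidate = consolidate),
                 n_samples = ncol(m$counts), n_peptides = nrow(m$counts),
                 call = cl),
            class = "paracne")
}

#' @export
print.paracne <- function(x, ...) {
  cat("pARACNe signaling network\n")
  cat("  ", nrow(x$network), " peptide-level edges, ",
      nrow(x$protein), " protein-level edges\n", sep = "")
  cat("  ", length(unique(x$protein$regulator)), " regulator kinases, ",
      x$params$B, " bootstraps, M = ", x$params$M, "\n", sep = "")
  invisible(x)
}

#' @export
summary.paracne <- function(object, ...) {
  rep <- negative_rho_report(object)
  tk <- object$tk_tk
  s <- list(
    n_peptide_edges = nrow(object$network),
    n_protein_edges = nrow(object$protein),
    n_regulators = length(unique(object$protein$regulator)),
    n_tk_tk = if (!is.null(tk)) tk$n_tk_tk else 0L,
    tk_tk_p = if (!is.null(tk)) tk$p else NA_real_,
    negative_rho = rep,
    mi_range = if (nrow(object$network)) range(object$network$mi) else c(NA, NA),
    params = object$params)
  class(s) <- "summary.paracne"
  s
}

#' @export
print.summary.paracne <- function(x, ...) {
  cat("pARACNe network summary\n")
  cat(sprintf("  peptide edges: %d   protein edges: %d   regulators: %d\n",
              x$n_peptide_edges, x$n_protein_edges, x$n_regulators))
  cat(sprintf("  TK-TK edges: %d (bias p = %.3g)\n", x$n_tk_tk, x$tk_tk_p))
  if (!is.na(x$negative_rho$fraction))
    cat(sprintf("  negative-rho edges: %d/%d (%.1f%%) at p <= 0.05\n",
                x$negative_rho$n_negative, x$negative_rho$n_edges,
                100 * x$negative_rho$fraction))
  if (!anyNA(x$mi_range))
    cat(sprintf("  MI range: %.3f .. %.3f nats\n", x$mi_range[1], x$mi_range[2]))
  invisible(x)
}

#' @export
plot.paracne <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (nrow(x$network)) {
    graphics::hist(x$network$mi, breaks = 20, col = "grey80",
                   main = "Edge mutual information", xlab = "MI (nats)")
    deg <- table(x$protein$regulator)
    graphics::barplot(sort(deg, decreasing = TRUE), las = 2,
                      main = "Substrates per kinase", ylab = "edges",
                      cex.names = 0.7)
  } else {
    graphics::plot.new(); graphics::title("empty network")
  }
  invisible(x)
}
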