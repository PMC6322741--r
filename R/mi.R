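#' Joint bin-count table
#'
#' Cross-tabulates two bin assignments over the same samples.
#'
#' @param x_bins,y_bins [iqd_discretize()] results (or plain integer label
#'   vectors) of equal length.
#' @return integer matrix `k_ij` (bins of X by bins of Y) with marginal
#'   sums consistent by construction.
#' @export
joint_count_table <- function(x_bins, y_bins) {
  xl <- if (inherits(x_bins, "bin_assignment")) x_bins$labels else as.integer(x_bins)
  yl <- if (inherits(y_bins, "bin_assignment")) y_bins$labels else as.integer(y_bins)
  if (length(xl) != length(yl))
    stop("bin assignments must have equal length", call. = FALSE)
  mx <- max(xl); my <- max(yl)
  matrix(tabulate((xl - 1L) * my + yl, mx * my), nrow = mx, ncol = my,
         byrow = TRUE)
}

#' Plug-in (bin-count) mutual information
#'
#' The histogram estimator on a joint count table: with `k_ij` joint
#' counts, marginals `k_i`, `k_j` and `N` samples,
#' \deqn{I(X,Y) = \log N + \frac{1}{N}\sum_{ij} k_{ij}
#'   \log\frac{k_{ij}}{k_i k_j}}
#' in nats, with `0 log 0 = 0`. Equals the Shannon MI of the empirical
#' joint distribution, hence is always non-negative and symmetric.
#'
#' @param t non-negative integer matrix of joint counts, or a list with
#'   elements `k_ij`, `k_i`, `k_j`, `N` (marginals are then checked for
#'   consistency).
#' @return mutual information in nats.
#' @examples
#' plugin_mi(matrix(c(2, 0, 0, 2), 2))  # log 2
#' @export
plugin_mi <- function(t) {
  if (is.list(t) && !is.data.frame(t)) {
    k <- as.matrix(t[["k_ij"]])
    ki <- t[["k_i"]]; kj <- t[["k_j"]]
    if (!is.null(ki) && !isTRUE(all.equal(unname(rowSums(k)),
                                          unname(as.numeric(ki)))))
      stop("row marginals inconsistent with k_ij", call. = FALSE)
    if (!is.null(kj) && !isTRUE(all.equal(unname(colSums(k)),
                                          unname(as.numeric(kj)))))
      stop("column marginals inconsistent with k_ij", call. = FALSE)
    if (!is.null(t[["N"]]) && sum(k) != t[["N"]])
      stop("N inconsistent with k_ij", call. = FALSE)
    t <- k
  }
  t <- as.matrix(t)
  if (any(t < 0)) stop("joint counts must be non-negative", call. = FALSE)
  N <- sum(t)
  if (N < 1) stop("empty joint table", call. = FALSE)
  ki <- rowSums(t)
  kj <- colSums(t)
  nz <- t > 0
  s <- sum(t[nz] * (log(t[nz]) - log(ki[row(t)[nz]]) - log(kj[col(t)[nz]])))
  mi <- log(N) + s / N
  max(mi, 0)                       # clamp tiny negative rounding residue
}

# MI directly from two label vectors.
mi_from_labels <- function(xl, yl) plugin_mi(joint_count_table(xl, yl))

#' Permutation p-value for a mutual-information score
#'
#' Permutes the Y labels `n_perm` times and reports
#' `p = (1 + #\{MI_perm >= MI_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams joint_count_table
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return list with `mi` (observed) and `p`.
#' @export
mi_pvalue <- function(x_bins, y_bins, n_perm = 1000, seed = 1) {
  xl <- if (inherits(x_bins, "bin_assignment")) x_bins$labels else as.integer(x_bins)
  yl <- if (inherits(y_bins, "bin_assignment")) y_bins$labels else as.integer(y_bins)
  if (length(xl) != length(yl))
    stop("bin assignments must have equal length", call. = FALSE)
  if (n_perm < 100) stop("'n_perm' must be >= 100", call. = FALSE)
  obs <- mi_from_labels(xl, yl)
  rng <- local_rng(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (mi_from_labels(xl, sample(yl)) >= obs) hits <- hits + 1L
  }
  list(mi = obs, p = (1 + hits) / (1 + n_perm))
}

# Scoped RNG: save/restore the global seed so package functions are
# reproducible without clobbering the caller's stream.
local_rng <- function(seed) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", globalenv())
  restore <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(restore, add = TRUE), envir = parent.frame())
  set.seed(as.integer(seed))
  invisible(seed)
}

# Pooled permutation null for edge significance. Draws `n_null` random
# (regulator row, target row) pairings from the discretized matrix, permutes
# the target labels, and fits an exponential upper tail
# log P(MI > x) = a + b x to the top `tail_frac` of null MIs (the classic
# ARACNe-style calibration; the chi-square limit of the G statistic makes
# the tail exponential). Returns the MI threshold for a given p-value and a
# p(mi) evaluator.
fit_mi_null <- function(bins_reg, bins_tgt, n_null = 3000, tail_frac = 0.15,
                        seed = 1) {
  local_rng(seed)
  nr <- length(bins_reg); nt <- length(bins_tgt)
  ri <- sample.int(nr, n_null, replace = TRUE)
  ti <- sample.int(nt, n_null, replace = TRUE)
  null_mi <- numeric(n_null)
  for (k in seq_len(n_null)) {
    null_mi[k] <- mi_from_labels(bins_reg[[ri[k]]]$labels,
                                 sample(bins_tgt[[ti[k]]]$labels))
  }
  s <- sort(null_mi, decreasing = TRUE)
  ntail <- max(30L, ceiling(tail_frac * n_null))
  x <- s[seq_len(ntail)]
  surv <- (seq_len(ntail)) / (n_null + 1)
  fit <- stats::lm(log(surv) ~ x)
  a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
  if (!is.finite(b) || b >= 0) {          # degenerate null (e.g. constant rows)
    a <- 0; b <- -Inf
  }
  list(
    threshold = function(p) if (is.infinite(b)) Inf else (log(p) - a) / b,
    pvalue = function(mi) pmin(1, exp(a + b * mi)),
    null_mi = null_mi
  )
}

#' Gold-standard-driven bin-number selection
#'
#' Sweeps the number of IQD bins `M`, infers a candidate network restricted
#' to genes present in the gold standard at each `M`, and scores gene-level
#' precision `TP/(TP+FP)` and sensitivity `TP/(TP+FN)` against the
#' gold-standard edges. The chosen `M` maximizes the F1 score (ties break
#' toward the smaller `M`). When no gold standard is available, `M = 10`
#' is the package default throughout.
#'
#' @param m a [count_matrix()].
#' @param gs gold standard data.frame (`kinase`, `substrate` gene columns),
#'   e.g. from [read_gold_standard()].
#' @param kinases character vector of tyrosine-kinase gene symbols.
#' @param M_range integer vector of bin numbers to sweep.
#' @param alpha edge-significance level (Bonferroni-corrected over pairs).
#' @param tolerance DPI tolerance.
#' @param seed RNG seed for the permutation null.
#' @return object of class `bin_sweep`: data.frame `sweep` with columns
#'   `M`, `precision`, `sensitivity`, `f1`, `edges`; and `chosen_M`.
#' @export
select_bin_number <- function(m, gs, kinases, M_range = 2:20, alpha = 0.05,
                              tolerance = 0, seed = 1) {
  stopifnot(inherits(m, "count_matrix"))
  if (!nrow(gs)) stop("gold standard is empty", call. = FALSE)
  gs$kinase <- normalize_gene(gs$kinase)
  gs$substrate <- normalize_gene(gs$substrate)
  kinases <- normalize_gene(kinases)
  gs_genes <- unique(c(gs$kinase, gs$substrate))
  keep <- m$peptides$gene %in% gs_genes
  if (!any(keep))
    stop("no matrix gene overlaps the gold standard", call. = FALSE)
  sub <- count_matrix(m$counts[keep, , drop = FALSE], classes = m$classes)
  if (!any(sub$peptides$gene %in% intersect(kinases, gs$kinase)))
    stop("no gold-standard kinase peptide present in the matrix", call. = FALSE)
  gs_key <- paste(gs$kinase, gs$substrate)
  rows <- lapply(M_range, function(M) {
    pred <- tryCatch({
      net <- infer_candidate_edges(sub, kinases, M = M, alpha = alpha,
                                   seed = seed)
      net <- apply_dpi(net, tolerance = tolerance)
      pn <- aggregate_to_protein(net)
      paste(pn$regulator, pn$substrate)
    }, error = function(e) character())
    tp <- sum(pred %in% gs_key)
    fp <- length(pred) - tp
    fn <- length(gs_key) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    data.frame(M = M, precision = prec, sensitivity = sens, f1 = f1,
               edges = length(pred))
  })
  sweep <- do.call(rbind, rows)
  chosen <- sweep$M[which.max(sweep$f1)]
  structure(list(sweep = sweep, chosen_M = chosen), class = "bin_sweep")
}

#' @export
print.bin_sweep <- function(x, ...) {
  cat("Bin-number sweep over M =", paste(range(x$sweep$M), collapse = ".."),
      "\n  chosen M =", x$chosen_M,
      sprintf("(precision %.2f, sensitivity %.2f)\n",
              x$sweep$precision[x$sweep$M == x$chosen_M],
              x$sweep$sensitivity[x$sweep$M == x$chosen_M]))
  invisible(x)
}
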