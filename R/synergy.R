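#' Excess Over Bliss
#'
#' The difference between the observed fractional inhibition of a drug
#' combination and the Bliss-independence expectation:
#' `EOB = fAB - (fA + fB - fA * fB)`. Positive values indicate
#' supra-additive (synergistic) interaction. All inputs are fractional
#' inhibitions in `[0, 1]`; use [viability_to_inhibition()] for viability
#' readouts.
#'
#' @param fA,fB fractional inhibition of each single agent.
#' @param fAB fractional inhibition of the combination.
#' @return excess over Bliss, in `[-1, 1]`.
#' @examples
#' excess_over_bliss(0.3, 0.4, 0.8)  # 0.22
#' @export
excess_over_bliss <- function(fA, fB, fAB) {
  v <- c(fA, fB, fAB)
  if (anyNA(v) || any(v < 0 | v > 1))
    stop("inhibition fractions must lie in [0, 1]", call. = FALSE)
  fAB - (fA + fB - fA * fB)
}

#' Convert fractional viability to fractional inhibition
#'
#' @param v viability in `[0, 1]` (1 = untreated control).
#' @return inhibition `1 - v`.
#' @export
viability_to_inhibition <- function(v) {
  if (anyNA(v) || any(v < 0 | v > 1))
    stop("viability must lie in [0, 1]", call. = FALSE)
  1 - v
}

#' IC50 by log-dose linear interpolation
#'
#' Finds the dose at which the response curve crosses 0.5, interpolating
#' linearly in log-dose between the bracketing design doses. Free of
#' curve-shape assumptions; suitable for the dense dose designs of MTT
#' assays.
#'
#' @param doses strictly increasing positive doses (in µM).
#' @param responses fractional viability in `[0, 1]` at each dose
#'   (replicate means).
#' @return the IC50 in the dose units; when the curve never reaches 0.5, a
#'   sentinel `NA` with attribute `censored = "> max dose"` (or
#'   `"< min dose"` when already below 0.5 at the lowest dose).
#' @examples
#' ic50_interpolate(c(0.1, 1, 10), c(1.0, 0.5, 0.1))  # 1
#' @export
ic50_interpolate <- function(doses, responses) {
  if (is.list(doses) || is.data.frame(doses)) {
    responses <- doses$responses
    doses <- doses$doses
  }
  if (any(diff(doses) <= 0) || any(doses <= 0))
    stop("doses must be positive and strictly increasing", call. = FALSE)
  if (anyNA(responses) || any(responses < 0 | responses > 1))
    stop("responses must lie in [0, 1]", call. = FALSE)
  below <- responses <= 0.5
  if (!any(below)) {
    out <- NA_real_
    attr(out, "censored") <- "> max dose"
    return(out)
  }
  if (below[1L]) {
    if (responses[1L] == 0.5) return(doses[1L])
    out <- NA_real_
    attr(out, "censored") <- "< min dose"
    return(out)
  }
  i <- which(below)[1L]            # first dose at or below 0.5
  if (responses[i] == 0.5) return(doses[i])
  x0 <- log(doses[i - 1L]); x1 <- log(doses[i])
  y0 <- responses[i - 1L]; y1 <- responses[i]
  exp(x0 + (0.5 - y0) * (x1 - x0) / (y1 - y0))
}

#' Chou-Talalay combination index
#'
#' `CI = d1/D1 + d2/D2`, where `d1`, `d2` are the doses of the two drugs
#' achieving the endpoint (IC50) in combination and `D1`, `D2` their
#' single-agent IC50s. Labels: `CI <= 0.8` strong synergy;
#' `0.8 < CI < 1` borderline synergy; `CI >= 1` additive or antagonistic.
#'
#' @param d1,d2 combination doses (positive).
#' @param D1,D2 single-agent IC50s (positive).
#' @return object of class `synergy_call`: list with `ci` and `label`.
#' @examples
#' combination_index(d1 = 0.5, D1 = 5, d2 = 0.96, D2 = 3)
#' @export
combination_index <- function(d1, D1, d2, D2) {
  v <- c(d1, D1, d2, D2)
  if (anyNA(v) || any(v <= 0))
    stop("doses and IC50s must be positive", call. = FALSE)
  ci <- d1 / D1 + d2 / D2
  structure(list(ci = ci, label = ci_label(ci)), class = "synergy_call")
}

#' Label a combination-index value
#'
#' @param ci positive combination index.
#' @return one of `"strong_synergy"` (CI <= 0.8), `"borderline"`
#'   (0.8 < CI < 1), `"additive_or_antagonistic"` (CI >= 1).
#' @export
ci_label <- function(ci) {
  if (anyNA(ci) || any(ci <= 0)) stop("'ci' must be positive", call. = FALSE)
  ifelse(ci <= 0.8, "strong_synergy",
         ifelse(ci < 1, "borderline", "additive_or_antagonistic"))
}

#' @export
print.synergy_call <- function(x, ...) {
  cat(sprintf("CI = %.3g (%s)\n", x$ci, x$label))
  invisible(x)
}

#' One-sided Fisher exact test
#'
#' Right-tail (enrichment direction) exact test on a 2x2 contingency
#' table: the hypergeometric probability of the observed top-left cell or
#' any more extreme table at fixed margins.
#'
#' @param table 2x2 matrix of non-negative integers with all margins
#'   positive.
#' @return the one-sided p-value.
#' @examples
#' fisher_exact_1sided(matrix(c(6, 2, 0, 6), 2))  # 28/3003
#' @export
fisher_exact_1sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all table margins must be positive", call. = FALSE)
  stats::fisher.test(table, alternative = "greater")$p.value
}

#' Combination-index table for a cell-line panel
#'
#' Computes the CI and synergy label per cell line from single-agent and
#' in-combination IC50s, mirroring the layout of an MTT summary table
#' (cell line, IC50 drug A, IC50 drug B, IC50 of B in combination with a
#' fixed dose of A).
#'
#' @param df data.frame with columns `cell_line`, `ic50_a`, `ic50_b`,
#'   `ic50_b_combo` and `dose_a_combo` (the fixed dose of drug A used in
#'   the combination arm; recycled if scalar).
#' @return `df` with `ci` and `label` columns added.
#' @export
ci_table <- function(df) {
  need <- c("cell_line", "ic50_a", "ic50_b", "ic50_b_combo", "dose_a_combo")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column '", miss[1L], "'", call. = FALSE)
  df$ci <- df$dose_a_combo / df$ic50_a + df$ic50_b_combo / df$ic50_b
  df$label <- ci_label(df$ci)
  df
}
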