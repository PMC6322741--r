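#' Iterative quantile discretization (IQD)
#'
#' Spectral counts are discrete, majority-zero and heavily tied, so
#' equal-width or plain quantile binning degenerates. IQD partitions the
#' `N` sorted values into `M` bins of as-equal-as-possible occupancy while
#' never splitting a group of tied values: whenever a tie group straddles a
#' bin boundary, the whole group is absorbed into the current bin, that bin
#' is closed, and the remaining points are re-partitioned over the
#' remaining bins. Iteration stops when bins or points run out.
#'
#' Conventions making the rule deterministic: samples are sorted by
#' `(count, original index)`; within one partition round of `n` points over
#' `m` bins, bin `b` closes at cumulative occupancy `round(b * n / m)`; a
#' straddling tie group is absorbed into the bin where its first sorted
#' member falls.
#'
#' @param x vector of non-negative integer counts (length >= 1).
#' @param M requested number of bins (>= 1).
#' @return an object of class `bin_assignment`: list with `labels` (integer
#'   bin label in `1..M_effective` per sample, original order),
#'   `M_requested`, and `M_effective` (number of non-empty bins actually
#'   produced, at most the number of distinct values).
#' @examples
#' iqd_discretize(c(0, 0, 0, 0, 0, 1, 2, 3), M = 4)
#' @export
iqd_discretize <- function(x, M) {
  if (length(M) != 1L || is.na(M) || M < 1)
    stop("'M' must be a single integer >= 1", call. = FALSE)
  M <- as.integer(M)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1L) stop("'x' must have length >= 1", call. = FALSE)
  if (anyNA(x) || any(x < 0)) stop("'x' must be non-negative counts", call. = FALSE)

  ord <- order(x, seq_len(n))        # stable: ties broken by original index
  v <- x[ord]
  lab <- integer(n)
  b <- 1L                            # global bin being filled
  i <- 1L                            # next unassigned position (sorted order)
  repeat {
    n_r <- n - i + 1L
    m_r <- M - b + 1L
    if (n_r <= 0L || m_r <= 0L) break
    # one partition round over the remaining points; restart on tie absorption
    start <- i
    j <- 1L                          # local bin index within this round
    repeat {
      if (b == M || j == m_r) {      # last bin takes everything left
        lab[i:n] <- b
        i <- n + 1L
        b <- b + 1L
        break
      }
      end <- start - 1L + as.integer(round(j * n_r / m_r))
      if (end < i) end <- i          # every bin gets at least one point
      straddle <- end < n && v[end + 1L] == v[end]
      while (end < n && v[end + 1L] == v[end]) end <- end + 1L
      lab[i:end] <- b
      i <- end + 1L
      b <- b + 1L
      if (straddle || i > n) break   # tie absorbed (or done): re-partition
      j <- j + 1L
    }
    if (i > n || b > M) break
  }

  labels <- integer(n)
  labels[ord] <- lab
  # relabel contiguously in case trailing bins stayed empty
  used <- sort(unique(lab))
  labels <- match(labels, used)
  structure(list(labels = labels, M_requested = M,
                 M_effective = length(used)),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat("IQD assignment:", length(x$labels), "samples,",
      x$M_effective, "of", x$M_requested, "bins used\n")
  occ <- tabulate(x$labels, x$M_effective)
  cat("  occupancy:", paste(occ, collapse = " "), "\n")
  invisible(x)
}

#' Row-wise IQD of a spectral-count matrix
#'
#' Applies [iqd_discretize()] independently to every peptide row.
#'
#' @param m a [count_matrix()] or a numeric matrix.
#' @param M requested bins per row.
#' @return list of `bin_assignment`, named by peptide id.
#' @export
discretize_matrix <- function(m, M) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  out <- vector("list", nrow(counts))
  names(out) <- rownames(counts)
  for (i in seq_len(nrow(counts))) {
    out[[i]] <- tryCatch(iqd_discretize(counts[i, ], M),
                         error = function(e)
                           stop("row '", rownames(counts)[i], "': ",
                                conditionMessage(e), call. = FALSE))
  }
  out
}
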