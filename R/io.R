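#' Spectral-count matrices
#'
#' The sole molecular input of the network-inference pipeline: a
#' peptides-by-samples matrix of non-negative integer MS/MS spectral counts.
#' Rows are phosphopeptides ([peptide_id()]); columns are samples, each
#' optionally tagged with a class (`tumor`, `cell_line`, or `normal`).
#' Missing cells are zeros: spectral counting reports absence as
#' non-detection.
#'
#' @param counts integer matrix (peptides x samples), non-negative, with
#'   unique row and column names. Row names are peptide ids in either
#'   dialect.
#' @param classes optional character vector (or named vector keyed by sample
#'   label) of sample classes in `c("tumor", "cell_line", "normal")`.
#' @param dialect dialect of the row names; auto-detected when `NULL`.
#' @return object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix, canonical dollar-dialect rownames), `peptides`
#'   (data.frame id/gene/sites) and `classes` (factor or NULL).
#' @seealso [read_count_matrix()], [write_count_matrix()]
#' @export
count_matrix <- function(counts, classes = NULL, dialect = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' needs peptide row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate peptide row id: '",
         rownames(counts)[duplicated(rownames(counts))][1L], "'", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample label: '",
         colnames(counts)[duplicated(colnames(counts))][1L], "'", call. = FALSE)
  counts[is.na(counts)] <- 0
  if (any(counts < 0))
    stop("negative spectral count in matrix", call. = FALSE)
  if (any(counts != round(counts)))
    stop("non-integer spectral count in matrix", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(dialect)) dialect <- detect_dialect(rownames(counts))
  peptides <- parse_peptide_ids(rownames(counts), dialect)
  if (anyDuplicated(peptides$id))
    stop("duplicate peptide row id after normalization: '",
         peptides$id[duplicated(peptides$id)][1L], "'", call. = FALSE)
  rownames(counts) <- peptides$id
  if (!is.null(classes)) {
    if (!is.null(names(classes))) {
      miss <- setdiff(colnames(counts), names(classes))
      if (length(miss))
        stop("no class tag for sample '", miss[1L], "'", call. = FALSE)
      classes <- classes[colnames(counts)]
    }
    if (length(classes) != ncol(counts))
      stop("'classes' length must match the number of samples", call. = FALSE)
    classes <- factor(as.character(classes),
                      levels = c("tumor", "cell_line", "normal"))
    if (anyNA(classes))
      stop("sample classes must be tumor, cell_line or normal", call. = FALSE)
    names(classes) <- colnames(counts)
  }
  structure(list(counts = counts, peptides = peptides, classes = classes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Spectral-count matrix:", nrow(x$counts), "peptides x",
      ncol(x$counts), "samples\n")
  cat("  genes:", length(unique(x$peptides$gene)),
      " zero cells:", sprintf("%.1f%%", 100 * mean(x$counts == 0)), "\n")
  if (!is.null(x$classes))
    cat("  classes:", paste(sprintf("%s=%d", levels(x$classes),
                                    tabulate(x$classes, 3L)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a spectral-count matrix from TSV
#'
#' Expects a header row of sample labels and a first column of peptide ids.
#' Blank cells are imputed as zero. Sample class tags come from a
#' two-column sidecar TSV (`label<TAB>class`, no header required) given via
#' `classes`.
#'
#' @param path TSV file.
#' @param dialect id dialect; auto-detected from the first data row when
#'   `NULL`. Mixed dialects in one file are rejected.
#' @param classes optional path to the class sidecar TSV, or a named vector.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, dialect = NULL, classes = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (ncol(df) < 2L) stop("count matrix needs an id column plus samples", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate peptide row id: '", ids[duplicated(ids)][1L], "'", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (is.character(m)) {
    mm <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                  dimnames = dimnames(m)))
    if (any(is.na(mm) & !is.na(m)))
      stop("non-numeric spectral count in matrix", call. = FALSE)
    m <- mm
  }
  rownames(m) <- ids
  if (is.null(dialect)) {
    dialect <- detect_dialect(ids[1L])
    has_dollar <- grepl("$", ids, fixed = TRUE)
    if ((dialect == "dollar" && !all(has_dollar)) ||
        (dialect == "underscore" && any(has_dollar)))
      stop("mixed peptide-id dialects in '", path, "'", call. = FALSE)
  }
  if (is.character(classes) && length(classes) == 1L && file.exists(classes))
    classes <- read_sample_classes(classes)
  count_matrix(m, classes = classes, dialect = dialect)
}

#' Read a sample-class sidecar file
#'
#' @param path two-column TSV (sample label, class); a header line
#'   `label<TAB>class` is permitted.
#' @return named character vector of classes.
#' @export
read_sample_classes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) && identical(tolower(df[1L, 1L]), "label")) df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 2L) stop("class sidecar needs two columns", call. = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a spectral-count matrix to TSV
#'
#' @param m a [count_matrix()].
#' @param path output file.
#' @param dialect dialect for the id column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, dialect = c("dollar", "underscore")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "count_matrix"))
  ids <- vapply(seq_len(nrow(m$counts)), function(i)
    format_peptide_id(peptide_id(m$peptides$gene[i], m$peptides$sites[[i]]),
                      dialect), "")
  df <- data.frame(peptide = ids, m$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tyrosine-kinase gene list
#'
#' One symbol per line; symbols are normalized through the alias map and
#' deduplicated.
#'
#' @param path text file.
#' @return character vector of kinase gene symbols.
#' @export
read_kinase_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(normalize_gene(x[nzchar(x)]))
}

#' Read a gold-standard kinase-substrate edge list
#'
#' @param path two-column TSV (kinase gene, substrate gene); a header is
#'   permitted and detected by the literal first cell `kinase`.
#' @return data.frame with columns `kinase`, `substrate` (normalized,
#'   deduplicated). Autophosphorylation rows (kinase == substrate) are kept.
#' @export
read_gold_standard <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) && identical(tolower(df[1L, 1L]), "kinase")) df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 2L) stop("gold standard needs two columns", call. = FALSE)
  gs <- data.frame(kinase = normalize_gene(df[[1L]]),
                   substrate = normalize_gene(df[[2L]]),
                   stringsAsFactors = FALSE)
  unique(gs)
}

#' Write a signaling network as a three-column TSV
#'
#' At the peptide level the regulator column uses the dollar dialect and the
#' substrate column the underscore dialect. At the protein level both
#' columns are bare gene symbols and the MI column carries the maximum
#' mutual information over contributing peptide-level edges.
#'
#' @param net a `paracne` fit or a data.frame of edges with columns
#'   `regulator`, `substrate` (canonical dollar-dialect peptide ids) and
#'   `mi`.
#' @param path output file.
#' @param level `"peptide"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, level = c("peptide", "protein")) {
  level <- match.arg(level)
  edges <- if (inherits(net, "paracne")) net$network else as.data.frame(net)
  if (!nrow(edges)) stop("cannot write an empty network", call. = FALSE)
  reformat <- function(ids, dialect) vapply(ids, function(id)
    format_peptide_id(parse_peptide_id(id, "dollar"), dialect), "")
  if (level == "peptide") {
    out <- data.frame(regulator = reformat(edges$regulator, "dollar"),
                      substrate = reformat(edges$substrate, "underscore"),
                      mi = edges$mi)
  } else {
    pn <- aggregate_to_protein(edges)
    out <- data.frame(regulator = pn$regulator, substrate = pn$substrate,
                      mi = pn$mi)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network TSV written by [write_network()]
#'
#' @param path three-column TSV.
#' @param level `"peptide"` or `"protein"`.
#' @return data.frame with columns `regulator`, `substrate` (canonical
#'   dollar ids at peptide level, gene symbols at protein level) and `mi`.
#' @export
read_network <- function(path, level = c("peptide", "protein")) {
  level <- match.arg(level)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("network file needs three columns", call. = FALSE)
  names(df)[1:3] <- c("regulator", "substrate", "mi")
  if (level == "peptide") {
    df$regulator <- vapply(df$regulator, function(id)
      format_peptide_id(parse_peptide_id(id, "dollar"), "dollar"), "")
    df$substrate <- vapply(df$substrate, function(id)
      format_peptide_id(parse_peptide_id(id, "underscore"), "dollar"), "")
  }
  df
}

#' Validate a spectral-count matrix file
#'
#' Checks parseability, row/column uniqueness, and integrality, and prints a
#' short summary. Used by the `validate` CLI subcommand.
#'
#' @inheritParams read_count_matrix
#' @return the parsed [count_matrix()], invisibly.
#' @export
validate_count_matrix <- function(path, dialect = NULL, classes = NULL) {
  m <- read_count_matrix(path, dialect = dialect, classes = classes)
  print(m)
  invisible(m)
}
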