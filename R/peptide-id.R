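#' Phosphopeptide identifiers
#'
#' A phosphopeptide is identified by an HGNC-style gene symbol plus one or
#' more tyrosine residue positions. Two serialization dialects are in common
#' use in supplementary tables of phosphoproteomic studies: the *dollar*
#' dialect (`EGFR$1197`, multi-site `ABC$10$25`) and the *underscore* dialect
#' (`MET_1003`). Both round-trip losslessly through [parse_peptide_id()] and
#' [format_peptide_id()].
#'
#' @param gene gene symbol (non-empty string); normalized via the package
#'   alias map (e.g. `"c-MET"` becomes `"MET"`).
#' @param sites integer vector of positive residue positions; stored sorted
#'   ascending.
#' @return an object of class `peptide_id`: a list with elements `gene` and
#'   `sites`.
#' @examples
#' peptide_id("EGFR", 1197)
#' parse_peptide_id("MET_1003", dialect = "underscore")
#' @export
peptide_id <- function(gene, sites) {
  gene <- normalize_gene(gene)
  if (!is.character(gene) || length(gene) != 1L || is.na(gene) || !nzchar(gene))
    stop("'gene' must be a single non-empty string", call. = FALSE)
  sites <- as.integer(sites)
  if (length(sites) < 1L || anyNA(sites) || any(sites <= 0L))
    stop("'sites' must be one or more positive integers", call. = FALSE)
  sites <- sort(unique(sites))
  structure(list(gene = gene, sites = sites), class = "peptide_id")
}

#' @export
print.peptide_id <- function(x, ...) {
  cat("<peptide>", format_peptide_id(x, "dollar"), "\n")
  invisible(x)
}

#' @export
format.peptide_id <- function(x, ...) format_peptide_id(x, "dollar")

#' @export
`==.peptide_id` <- function(e1, e2) {
  identical(e1$gene, e2$gene) && identical(e1$sites, e2$sites)
}

# Gene-symbol alias map. Common literature aliases for receptor/cytoplasmic
# tyrosine kinases; comparison is case-insensitive after trimming.
.gene_aliases <- c(
  "C-MET" = "MET", "C-KIT" = "KIT", "C-SRC" = "SRC", "C-ABL" = "ABL1",
  "C-FMS" = "CSF1R", "C-YES" = "YES1", "HER2" = "ERBB2", "HER3" = "ERBB3",
  "HER4" = "ERBB4", "ABL" = "ABL1", "JAK-2" = "JAK2"
)

#' Normalize a gene symbol
#'
#' Trims whitespace, upper-cases, and resolves a small map of literature
#' aliases (`c-MET` -> `MET`, `HER2` -> `ERBB2`, ...). Symbols are always
#' compared after this normalization.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_gene <- function(x) {
  x <- toupper(trimws(as.character(x)))
  hit <- match(x, names(.gene_aliases))
  x[!is.na(hit)] <- .gene_aliases[hit[!is.na(hit)]]
  x
}

.dialect_sep <- c(dollar = "$", underscore = "_")

#' Parse a serialized phosphopeptide identifier
#'
#' @param text string of the form `GENE$s1[$s2...]` (dollar dialect) or
#'   `GENE_s1[_s2...]` (underscore dialect).
#' @param dialect `"dollar"` or `"underscore"`.
#' @return a [peptide_id()].
#' @examples
#' parse_peptide_id("EGFR$1197", "dollar")
#' parse_peptide_id("ABC$10$25", "dollar")
#' @export
parse_peptide_id <- function(text, dialect = c("dollar", "underscore")) {
  dialect <- match.arg(dialect)
  sep <- .dialect_sep[[dialect]]
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single string", call. = FALSE)
  parts <- strsplit(text, sep, fixed = TRUE)[[1L]]
  if (length(parts) < 2L)
    stop("malformed peptide id '", text, "': no phosphosite after the gene symbol",
         call. = FALSE)
  gene <- parts[1L]
  if (!nzchar(gene))
    stop("malformed peptide id '", text, "': empty gene symbol", call. = FALSE)
  site_tok <- parts[-1L]
  bad <- !grepl("^[0-9]+$", site_tok)
  if (any(bad))
    stop("malformed peptide id '", text, "': non-numeric site '",
         site_tok[bad][1L], "'", call. = FALSE)
  peptide_id(gene, as.integer(site_tok))
}

#' Serialize a phosphopeptide identifier
#'
#' @param p a [peptide_id()].
#' @inheritParams parse_peptide_id
#' @return string in the requested dialect.
#' @export
format_peptide_id <- function(p, dialect = c("dollar", "underscore")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(p, "peptide_id"))
  paste(c(p$gene, p$sites), collapse = .dialect_sep[[dialect]])
}

# Vectorized parse of a character vector of ids; returns data.frame with
# columns id (canonical dollar form), gene, sites (list column).
parse_peptide_ids <- function(ids, dialect) {
  ps <- lapply(ids, parse_peptide_id, dialect = dialect)
  data.frame(
    id = vapply(ps, format_peptide_id, "", dialect = "dollar"),
    gene = vapply(ps, `[[`, "", "gene"),
    sites = I(lapply(ps, `[[`, "sites")),
    stringsAsFactors = FALSE
  )
}

# Guess the dialect from the first data row: a '$' anywhere means dollar.
detect_dialect <- function(ids) {
  if (any(grepl("$", ids, fixed = TRUE))) "dollar" else "underscore"
}
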