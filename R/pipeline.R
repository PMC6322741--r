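#' Run the full inference pipeline
#'
#' Wires the stages end to end: (optionally) simulate a dataset or read a
#' count matrix, infer the bootstrap-consolidated network, run the
#' master-regulator analysis, and write the artifacts — peptide- and
#' protein-level network TSVs, a long-format MR table, and a plain-text
#' manifest recording seeds, parameters and per-stage counts.
#'
#' @param config named list (or path to a YAML file, requires the `yaml`
#'   package) with entries:
#'   \describe{
#'     \item{matrix, classes, kinases}{input file paths; or}
#'     \item{simulate}{a list of [sim_config()] arguments (then inputs are
#'       generated and also written next to the outputs)}
#'     \item{out_dir}{output directory (created if needed)}
#'     \item{M, alpha, tolerance, B, n_perm, seed, dialect}{stage
#'       parameters; all optional}
#'     \item{viper}{logical, run the MR stage (default TRUE)}
#'   }
#' @return invisibly, a list with `fit` (`paracne`), `mr` (`pviper` or
#'   NULL) and `manifest` (character vector of manifest lines).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  get_par <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  out_dir <- get_par("out_dir", ".")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- get_par("seed", 1L)
  # manifest is deterministic under a fixed config (timestamps go to the
  # CLI log, not here) so reruns are byte-comparable
  manifest <- c(paste0("paracne ", as.character(utils::packageVersion("paracne"))),
                paste0("seed: ", seed))
  done <- character()
  on.exit({
    # abort cleanup: drop partial artifacts of the failed stage
    partial <- setdiff(list.files(out_dir, full.names = TRUE,
                                  pattern = "\\.partial$"), character())
    unlink(partial)
  })

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    m <- sim$matrix
    kinases <- sim$kinases
    write_count_matrix(m, file.path(out_dir, "matrix.tsv"))
    utils::write.table(sim$truth$edges[, c("regulator", "substrate")],
                       file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- c(manifest,
                  sprintf("simulate: %d TKs, %d substrates, %d samples",
                          sim$config$n_tk, sim$config$n_substrates,
                          sum(sim$config$n_samples)))
  } else {
    if (is.null(cfg$matrix) || !file.exists(cfg$matrix))
      stop("configuration error at stage 'input': count matrix file not found",
           call. = FALSE)
    if (is.null(cfg$kinases) || !file.exists(cfg$kinases))
      stop("configuration error at stage 'input': kinase list file not found",
           call. = FALSE)
    m <- read_count_matrix(cfg$matrix, dialect = get_par("dialect", NULL),
                           classes = get_par("classes", NULL))
    kinases <- read_kinase_list(cfg$kinases)
  }
  manifest <- c(manifest,
                sprintf("input: %d peptides x %d samples, %d kinase symbols",
                        nrow(m$counts), ncol(m$counts), length(kinases)))

  fit <- tryCatch(
    paracne(m, kinases, M = get_par("M", 10), alpha = get_par("alpha", 0.05),
            tolerance = get_par("tolerance", 0), B = get_par("B", 100),
            seed = seed, n_null = get_par("n_null", 3000)),
    error = function(e) stop("stage 'infer' failed: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(fit$network)) {
    write_network(fit, file.path(out_dir, "network_peptide.tsv"), "peptide")
    write_network(fit, file.path(out_dir, "network_protein.tsv"), "protein")
  }
  manifest <- c(manifest,
                sprintf("infer: %d peptide edges, %d protein edges, M=%d B=%d",
                        nrow(fit$network), nrow(fit$protein),
                        fit$params$M, fit$params$B))

  mr <- NULL
  if (isTRUE(get_par("viper", TRUE)) && !is.null(m$classes) &&
      sum(m$classes == "normal") >= 2 && nrow(fit$network)) {
    samples <- get_par("viper_samples",
                       colnames(m$counts)[m$classes == "cell_line"])
    mr <- tryCatch(
      pviper(m, fit, samples = samples, pairs = get_par("pairs", NULL),
             n_perm = get_par("n_perm", 1000), seed = seed),
      error = function(e) stop("stage 'viper' failed: ", conditionMessage(e),
                               call. = FALSE))
    out <- mr$protein
    utils::write.table(out, file.path(out_dir, "mr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- c(manifest,
                  sprintf("viper: %d samples, %d significant calls",
                          length(unique(out$sample)),
                          sum(out$significant, na.rm = TRUE)))
  }

  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(manifest, manifest_path)
  on.exit()                                 # success: no cleanup
  invisible(list(fit = fit, mr = mr, manifest = manifest))
}
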