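#' Configuration of the synthetic phosphoproteome generator
#'
#' Bundles the parameters of the ground-truth network and count generator.
#' Defaults emulate the character of a LUAD phosphotyrosine spectral-count
#' compendium: a few dozen tyrosine kinases among a much larger peptide
#' complement, a tumor/cell-line/normal sample mix, majority-zero counts
#' with an overdispersed low-abundance tail, and predominantly positive
#' kinase-substrate phospho-state coupling.
#'
#' @param n_tk number of tyrosine-kinase genes.
#' @param n_substrates number of non-kinase substrate genes (a subset stays
#'   unconnected, providing null rows).
#' @param n_samples named integer vector `c(tumor=, cell_line=, normal=)`.
#' @param edges_per_tk substrates wired to each kinase (exact out-degree).
#' @param n_tk_tk_edges planted kinase-to-kinase edges.
#' @param synergy_pairs number of designated synergistic kinase pairs.
#' @param shared_substrate_fraction fraction of a synergistic pair's
#'   substrates that are shared between the two kinases.
#' @param zero_inflation target zero-count probability of a baseline
#'   (inactive) peptide; the negative-binomial baseline mean is solved from
#'   it, so `1` yields an all-zero matrix.
#' @param count_dispersion negative-binomial size parameter (smaller =
#'   more overdispersed).
#' @param coupling_strength latent kinase-substrate correlation in `[0, 1]`.
#' @param negative_edge_fraction fraction of kinase-substrate edges with
#'   inverted (negative) coupling.
#' @param multi_peptide_fraction fraction of genes emitting two phosphosite
#'   peptides with correlated latents.
#' @param latent_scale log-rate units per latent standard deviation.
#' @param normal_sd latent activity standard deviation of normal-class
#'   samples (tumors and cell lines have sd 1).
#' @param spike_samples,spike_tks,spike_magnitude optional activity spikes:
#'   the named kinases' latent activity is raised by `spike_magnitude` in
#'   the named samples, whose background activity sits at the normal
#'   baseline (used to plant master-regulator signal).
#' @param spike_substrates optional substrate-level spike: the named
#'   substrate genes' latents are raised by `spike_magnitude` in
#'   `spike_samples` (used to plant shared-substrate hyperphosphorylation,
#'   the synergistic-pair scenario).
#' @param seed mandatory RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_tk = 10, n_substrates = 100,
                       n_samples = c(tumor = 156, cell_line = 46, normal = 48),
                       edges_per_tk = 8, n_tk_tk_edges = 2,
                       synergy_pairs = 1, shared_substrate_fraction = 0.25,
                       zero_inflation = 0.6, count_dispersion = 4,
                       coupling_strength = 0.8, negative_edge_fraction = 0,
                       multi_peptide_fraction = 0.15, latent_scale = 2.5,
                       normal_sd = 0.25, spike_samples = character(),
                       spike_tks = character(), spike_substrates = character(),
                       spike_magnitude = 3, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  n_samples <- unlist(n_samples)           # accept YAML/list sample maps
  fr <- c(shared_substrate_fraction, zero_inflation, coupling_strength,
          negative_edge_fraction, multi_peptide_fraction)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (n_tk < 1 || n_substrates < 1 || any(n_samples < 0) || edges_per_tk < 1)
    stop("counts must be positive", call. = FALSE)
  if (is.null(names(n_samples)))
    names(n_samples) <- c("tumor", "cell_line", "normal")
  structure(list(
    n_tk = as.integer(n_tk), n_substrates = as.integer(n_substrates),
    n_samples = n_samples, edges_per_tk = as.integer(edges_per_tk),
    n_tk_tk_edges = as.integer(n_tk_tk_edges),
    synergy_pairs = as.integer(synergy_pairs),
    shared_substrate_fraction = shared_substrate_fraction,
    zero_inflation = zero_inflation, count_dispersion = count_dispersion,
    coupling_strength = coupling_strength,
    negative_edge_fraction = negative_edge_fraction,
    multi_peptide_fraction = multi_peptide_fraction,
    latent_scale = latent_scale, normal_sd = normal_sd,
    spike_samples = spike_samples, spike_tks = spike_tks,
    spike_substrates = spike_substrates,
    spike_magnitude = spike_magnitude, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a ground-truth signaling topology
#'
#' Builds a bipartite kinase-substrate graph with exact out-degree
#' `edges_per_tk`, a configured number of kinase-kinase edges, and
#' designated synergistic pairs sharing `shared_substrate_fraction` of
#' their substrate sets. Kinase genes are named `TK1..`, substrates
#' `SUB1..`.
#'
#' @param cfg a [sim_config()].
#' @return list with `edges` (data.frame `regulator`, `substrate` gene
#'   symbols, `type` in `ts`/`tt`, `sign`), `kinases`, `synergy_pairs`
#'   (data.frame `a`, `b`), and per-substrate parent map.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_rng(cfg$seed)
  tks <- paste0("TK", seq_len(cfg$n_tk))
  subs <- paste0("SUB", seq_len(cfg$n_substrates))
  if (cfg$edges_per_tk > cfg$n_substrates)
    stop("infeasible config: edges_per_tk exceeds n_substrates", call. = FALSE)
  n_shared <- round(cfg$shared_substrate_fraction * cfg$edges_per_tk)
  n_pairs <- min(cfg$synergy_pairs, floor(cfg$n_tk / 2))
  needed <- cfg$n_tk * cfg$edges_per_tk - n_pairs * n_shared
  if (needed > cfg$n_substrates)
    stop("infeasible config: ", needed, " distinct substrates required but only ",
         cfg$n_substrates, " available", call. = FALSE)
  pool <- sample(subs)                      # shuffled assignment order
  take <- function(k) {
    if (k <= 0) return(character())
    out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out
  }
  edges <- list()
  pair_df <- NULL
  assigned <- stats::setNames(vector("list", cfg$n_tk), tks)
  if (n_pairs > 0) {
    for (p in seq_len(n_pairs)) {
      a <- tks[2 * p - 1L]; b <- tks[2 * p]
      shared <- take(n_shared)
      ua <- take(cfg$edges_per_tk - n_shared)
      ub <- take(cfg$edges_per_tk - n_shared)
      assigned[[a]] <- c(shared, ua)
      assigned[[b]] <- c(shared, ub)
      pair_df <- rbind(pair_df, data.frame(a = a, b = b,
                                           n_shared = length(shared),
                                           stringsAsFactors = FALSE))
    }
  }
  rest <- setdiff(tks, unlist(pair_df[c("a", "b")]))
  for (tk in rest) assigned[[tk]] <- take(cfg$edges_per_tk)
  parents <- stats::setNames(vector("list", cfg$n_substrates), subs)
  for (tk in tks) for (s in assigned[[tk]])
    parents[[s]] <- c(parents[[s]], tk)
  for (tk in tks) {
    sg <- rep(1, length(assigned[[tk]]))
    if (cfg$negative_edge_fraction > 0) {
      nneg <- stats::rbinom(1L, length(sg), cfg$negative_edge_fraction)
      if (nneg > 0) sg[sample(length(sg), nneg)] <- -1
    }
    edges[[tk]] <- data.frame(regulator = tk, substrate = assigned[[tk]],
                              type = "ts", sign = sg, stringsAsFactors = FALSE)
  }
  # kinase-kinase edges: child activity driven by parent
  tk_parent <- stats::setNames(rep(NA_character_, cfg$n_tk), tks)
  n_tt <- min(cfg$n_tk_tk_edges, cfg$n_tk - 1L)
  if (n_tt > 0) {
    # avoid making synergy-pair members children (keeps their activities
    # independent, as the pair design assumes)
    pair_members <- unlist(pair_df[c("a", "b")])
    candidates <- setdiff(tks, pair_members)
    n_tt <- min(n_tt, max(0L, length(candidates) - 1L))
    if (n_tt > 0) {
      children <- sample(candidates, n_tt)
      for (ch in children) {
        par <- sample(setdiff(tks, c(ch, children)), 1L)
        tk_parent[ch] <- par
        edges[[paste0("tt_", ch)]] <-
          data.frame(regulator = par, substrate = ch, type = "tt", sign = 1,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(edges = do.call(rbind, edges), kinases = tks,
       synergy_pairs = pair_df, parents = parents, tk_parent = tk_parent,
       substrates = subs)
}

#' Simulate a spectral-count matrix from a ground-truth topology
#'
#' Latent model: each kinase has a per-sample activity (standard normal in
#' tumors and cell lines, `normal_sd` in normals, optionally spiked);
#' each substrate's latent equals `coupling_strength` times its parent
#' activity (the standardized parent sum for shared substrates) plus
#' Gaussian noise; unconnected substrates are pure noise. A configurable
#' fraction of genes emits two phosphosite peptides whose latents share
#' the gene latent. Counts are drawn from a negative binomial whose
#' log-mean is `latent_scale` times the peptide latent around a baseline
#' solved from `zero_inflation` (the zero-count probability of an inactive
#' peptide), reproducing the majority-zero, skewed low-abundance character
#' of spectral counting.
#'
#' @param truth a [simulate_truth()] result.
#' @param cfg the same [sim_config()].
#' @return a [count_matrix()] with class tags.
#' @export
simulate_counts <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_rng(cfg$seed + 1L)
  ns <- cfg$n_samples
  n_s <- sum(ns)
  labels <- c(sprintf("tumor_%03d", seq_len(ns[["tumor"]])),
              sprintf("cell_%03d", seq_len(ns[["cell_line"]])),
              sprintf("normal_%03d", seq_len(ns[["normal"]])))
  classes <- stats::setNames(rep(c("tumor", "cell_line", "normal"), ns), labels)
  is_normal <- classes == "normal"
  cc <- cfg$coupling_strength

  # kinase activities
  tks <- truth$kinases
  act <- matrix(stats::rnorm(length(tks) * n_s), length(tks), n_s,
                dimnames = list(tks, labels))
  act[, is_normal] <- act[, is_normal] * cfg$normal_sd
  for (ch in tks) {                        # kinase-kinase wiring
    par <- truth$tk_parent[[ch]]
    if (!is.na(par))
      act[ch, ] <- cc * act[par, ] + sqrt(1 - cc^2) * act[ch, ]
  }
  if (length(cfg$spike_samples)) {
    # a spiked sample models a cell line whose phospho-state aberration is
    # driven by the designated kinases: background TK activity sits at the
    # normal baseline, the designated TKs are elevated. With no designated
    # kinase the sample is a baseline (null) cell line.
    sp <- intersect(cfg$spike_samples, labels)
    act[, sp] <- act[, sp] * cfg$normal_sd
    for (tk in intersect(cfg$spike_tks, tks))
      act[tk, sp] <- act[tk, sp] + cfg$spike_magnitude
  }

  # substrate gene latents
  subs <- truth$substrates
  lat <- matrix(stats::rnorm(length(subs) * n_s), length(subs), n_s,
                dimnames = list(subs, labels))
  ed <- truth$edges[truth$edges$type == "ts", , drop = FALSE]
  for (s in subs) {
    par <- ed[ed$substrate == s, , drop = FALSE]
    if (!nrow(par)) next                   # unconnected: pure noise
    drive <- rep(0, n_s)
    for (i in seq_len(nrow(par)))
      drive <- drive + par$sign[i] * act[par$regulator[i], ]
    drive <- drive / sqrt(nrow(par))
    lat[s, ] <- cc * drive + sqrt(1 - cc^2) * lat[s, ]
  }
  if (length(cfg$spike_samples) && length(cfg$spike_substrates)) {
    sp <- intersect(cfg$spike_samples, labels)
    ss <- intersect(cfg$spike_substrates, subs)
    lat[ss, sp] <- lat[ss, sp] + cfg$spike_magnitude
  }

  # peptides: genes in row order TKs then substrates; a fraction get 2 sites
  genes <- c(tks, subs)
  glat <- rbind(act, lat)
  n_multi <- round(cfg$multi_peptide_fraction * length(genes))
  multi <- if (n_multi > 0) sample(genes, n_multi) else character()
  w <- 0.7                                 # peptide-gene latent sharing
  pep_gene <- character(); pep_site <- integer(); pep_lat <- list()
  for (g in genes) {
    k <- if (g %in% multi) 2L else 1L
    sites <- sort(sample(100:1400, k))
    for (j in seq_len(k)) {
      pep_gene <- c(pep_gene, g)
      pep_site <- c(pep_site, sites[j])
      pl <- if (k == 1L) glat[g, ] else
        sqrt(w) * glat[g, ] + sqrt(1 - w) * stats::rnorm(n_s)
      pep_lat[[length(pep_lat) + 1L]] <- pl
    }
  }
  ids <- paste0(pep_gene, "$", pep_site)

  # counts: NB around a baseline mean solved from the zero-inflation target
  size <- cfg$count_dispersion
  mu0 <- if (cfg$zero_inflation >= 1) 0 else
    size * (cfg$zero_inflation^(-1 / size) - 1)
  counts <- matrix(0L, length(ids), n_s, dimnames = list(ids, labels))
  for (i in seq_along(ids)) {
    # soft-saturating activity: phosphosite occupancy cannot grow without
    # bound, which also keeps counts in the observed spectral-count range
    eff <- 2.5 * tanh(pep_lat[[i]] / 2.5)
    mu <- mu0 * exp(cfg$latent_scale * eff)
    counts[i, ] <- stats::rnbinom(n_s, size = size, mu = mu)
  }
  count_matrix(counts, classes = classes)
}

#' Simulate a complete synthetic dataset
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` ([count_matrix()]), `truth`
#'   ([simulate_truth()]), `kinases`, and `config`.
#' @export
simulate_dataset <- function(cfg) {
  truth <- simulate_truth(cfg)
  m <- simulate_counts(truth, cfg)
  list(matrix = m, truth = truth, kinases = truth$kinases, config = cfg)
}

#' Gene-level recovery of a planted network
#'
#' Compares a fitted protein-level network against the generator's truth.
#' Kinase-kinase edges are compared unordered (MI is symmetric, so the
#' inferred direction of a TK-TK edge is arbitrary); same-gene
#' (autophosphorylation-like) predictions are dropped from both sides
#' unless `include_auto`.
#'
#' @param fit a `paracne` fit, or a protein-level edge data.frame.
#' @param truth a [simulate_truth()] result.
#' @param include_auto keep same-gene edges in the comparison.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
evaluate_recovery <- function(fit, truth, include_auto = FALSE) {
  pn <- if (inherits(fit, "paracne")) fit$protein else as.data.frame(fit)
  kin <- truth$kinases
  canon <- function(r, s) {
    tt <- r %in% kin & s %in% kin
    a <- ifelse(tt, pmin(r, s), r)
    b <- ifelse(tt, pmax(r, s), s)
    paste(a, b)
  }
  pred <- canon(pn$regulator, pn$substrate)
  if (!include_auto) pred <- pred[pn$regulator != pn$substrate]
  tr <- canon(truth$edges$regulator, truth$edges$substrate)
  pred <- unique(pred); tr <- unique(tr)
  tp <- sum(pred %in% tr)
  list(tp = tp, fp = length(pred) - tp, fn = length(tr) - tp,
       precision = if (length(pred)) tp / length(pred) else NA_real_,
       recall = tp / length(tr))
}
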