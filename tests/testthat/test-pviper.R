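panel_cfg <- function(seed, ...) {
  sim_config(n_tk = 8, n_substrates = 70,
             n_samples = c(tumor = 120, cell_line = 10, normal = 30),
             seed = seed, ...)
}

test_that("signatures center on the normal reference and use the sd floor", {
  counts <- rbind(
    "A$1" = c(2L, 2L, 2L, 2L, 7L),   # constant in normals: floored sd
    "B$1" = c(0L, 2L, 4L, 6L, 3L),   # varying normals
    "C$1" = c(1L, 3L, 1L, 3L, 2L))
  colnames(counts) <- c(paste0("n", 1:4), "cl")
  m <- count_matrix(counts, classes = c(rep("normal", 4), "cell_line"))
  sig <- compute_signature(m, "cl")
  s0 <- median(c(sd(c(0, 2, 4, 6)), sd(c(1, 3, 1, 3))))
  expect_equal(sig$sd_floor, s0)
  expect_equal(unname(sig$scores["A$1"]), 5 / s0)
  expect_equal(unname(sig$scores["B$1"]), 0)  # equals the normal mean

  expect_error(compute_signature(m, "nope"), "unknown sample")
  m2 <- count_matrix(counts, classes = c("normal", rep("tumor", 3), "cell_line"))
  expect_error(compute_signature(m2, "cl"), "two normal")
})

test_that("signalon correlation filter applies Bonferroni per regulator", {
  # pre-annotated edges: p = 0.04 uncorrected among 10 candidates fails
  # the 0.005 Bonferroni cut; p = 0.004 passes
  edges <- data.frame(
    regulator = rep("K$1", 10),
    substrate = sprintf("S%d$1", 1:10),
    mi = 1, rho = c(0.9, -0.8, rep(0.3, 8)),
    rho_p = c(0.004, 0.001, 0.04, rep(0.5, 7)),
    rho_defined = TRUE, stringsAsFactors = FALSE)
  counts <- matrix(rpois(11 * 6, 2), 11, 6,
                   dimnames = list(c("K$1", sprintf("S%d$1", 1:10)),
                                   paste0("s", 1:6)))
  m <- count_matrix(counts)
  sgl <- build_signalons(edges, m)
  tg <- sgl[["K$1"]]$targets
  expect_equal(nrow(tg), 2)
  expect_true("S1$1" %in% tg$substrate)          # 0.004 * 10 <= 0.05
  expect_false("S3$1" %in% tg$substrate)         # 0.04 * 10 > 0.05
  # negative-correlation target retained in the type with its sign
  expect_equal(tg$sign[tg$substrate == "S2$1"], -1)
  expect_equal(tg$weight[tg$substrate == "S2$1"], 0.8)
})

test_that("negative-sign targets are plentiful only with planted negative edges", {
  sim_pos <- simulate_dataset(panel_cfg(31))
  sgl <- build_signalons(truth_peptide_edges(sim_pos), sim_pos$matrix)
  tg <- do.call(rbind, lapply(sgl, `[[`, "targets"))
  expect_gt(nrow(tg), 20)
  expect_lt(mean(tg$sign < 0), 0.05)

  sim_neg <- simulate_dataset(panel_cfg(31, negative_edge_fraction = 0.5))
  sgl_n <- build_signalons(truth_peptide_edges(sim_neg), sim_neg$matrix)
  tg_n <- do.call(rbind, lapply(sgl_n, `[[`, "targets"))
  expect_gt(mean(tg_n$sign < 0), 0.2)
})

test_that("enrichment ES matches the literal running-sum oracle", {
  set.seed(44)
  for (i in 1:30) {
    N <- sample(c(40, 90), 1)
    scores <- stats::setNames(rnorm(N), sprintf("P%03d$1", 1:N))
    k <- sample(3:12, 1)
    targets <- sample(names(scores), k)
    weights <- runif(k, 0.3, 1)
    s <- list(targets = data.frame(substrate = targets, sign = 1,
                                   weight = weights, stringsAsFactors = FALSE))
    en <- enrichment_nes(scores, s, n_perm = 100, seed = i)
    expect_lt(abs(en$es - gsea_oracle(scores, targets, weights)), 1e-12)
  }
})

test_that("top-ranked targets give maximal positive enrichment", {
  scores <- stats::setNames(seq(5, -5, length.out = 50), sprintf("P%02d$1", 1:50))
  s <- list(targets = data.frame(substrate = names(scores)[1:6], sign = 1,
                                 weight = 1, stringsAsFactors = FALSE))
  en <- enrichment_nes(scores, s, n_perm = 300, seed = 2)
  expect_gt(en$es, 0.85)
  expect_gt(en$nes, 0)
  expect_lte(en$p, 0.02)
})

test_that("negating the signature negates the enrichment sign", {
  set.seed(50)
  scores <- stats::setNames(rnorm(80), sprintf("P%03d$1", 1:80))
  s <- list(targets = data.frame(substrate = sample(names(scores), 8), sign = 1,
                                 weight = runif(8, 0.4, 1),
                                 stringsAsFactors = FALSE))
  a <- enrichment_nes(scores, s, n_perm = 200, seed = 5)
  b <- enrichment_nes(-scores, s, n_perm = 200, seed = 5)
  expect_equal(b$es, -a$es, tolerance = 1e-8)
  expect_equal(sign(b$nes), -sign(a$nes))
})

test_that("NES is standardized against its permutation null", {
  set.seed(52)
  scores <- stats::setNames(rnorm(100), sprintf("P%03d$1", 1:100))
  nes <- vapply(1:60, function(i) {
    s <- list(targets = data.frame(substrate = sample(names(scores), 10),
                                   sign = 1, weight = 1,
                                   stringsAsFactors = FALSE))
    enrichment_nes(scores, s, n_perm = 300, seed = 900 + i)$nes
  }, 0)
  expect_lt(abs(mean(nes)), 0.3)
  expect_lt(abs(sd(nes) - 1), 0.35)
  expect_gt(mean(abs(nes) < 2), 0.9)
})

test_that("empty or negative-only signalons yield flagged null results", {
  scores <- stats::setNames(rnorm(20), sprintf("P%02d$1", 1:20))
  s_neg <- list(targets = data.frame(substrate = names(scores)[1:3], sign = -1,
                                     weight = 1, stringsAsFactors = FALSE))
  en <- enrichment_nes(scores, s_neg, n_perm = 100, seed = 1)
  expect_true(en$empty)
  expect_true(is.na(en$nes))
})

test_that("protein-level combination follows Stouffer across peptides", {
  # two peptides of one kinase with identical evidence combine to sqrt(2) z
  counts <- matrix(rpois(8 * 40, 3), 8, 40,
                   dimnames = list(c("K$1", "K$2", sprintf("S%d$1", 1:6)),
                                   paste0("s", 1:40)))
  m <- count_matrix(counts, classes = c(rep("normal", 20), rep("cell_line", 20)))
  edges <- data.frame(regulator = rep(c("K$1", "K$2"), each = 6),
                      substrate = rep(sprintf("S%d$1", 1:6), 2),
                      mi = 1, rho = 0.9, rho_p = 1e-6, rho_defined = TRUE,
                      stringsAsFactors = FALSE)
  mr <- pviper(m, edges, samples = "s21", n_perm = 200, seed = 3)
  pep <- mr$peptide
  expect_equal(nrow(pep), 2)
  prot <- mr$protein
  expect_equal(prot$nes, sum(pep$nes) / sqrt(2))
  zp <- sign(pep$nes) * qnorm(1 - pep$p / 2)
  expect_equal(prot$z, sum(zp) / sqrt(2))
})

test_that("a spiked kinase tops the per-sample master-regulator ranking", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_dataset(panel_cfg(700 + s, spike_tks = "TK3",
                                      spike_samples = "cell_001"))
    mr <- pviper(sim$matrix, truth_peptide_edges(sim), samples = "cell_001",
                 n_perm = 500, seed = s)
    hits <- hits + (mr$protein$gene[1] == "TK3")
  }
  expect_gte(hits, 8)
})

test_that("pair synergy flags empty intersections and detects planted sharing", {
  scores <- stats::setNames(rnorm(60), sprintf("P%02d$1", 1:60))
  mk <- function(subs) list(targets = data.frame(substrate = subs, sign = 1,
                                                 weight = 1,
                                                 stringsAsFactors = FALSE))
  disjoint <- pair_synergy(scores, mk(names(scores)[1:5]),
                           mk(names(scores)[6:10]), n_perm = 100, seed = 1)
  expect_true(disjoint$empty)
  expect_equal(disjoint$n_shared, 0)

  # shared targets at the very top, unique targets scattered
  ord <- names(sort(scores, decreasing = TRUE))
  shared <- ord[1:5]
  uniqA <- sample(ord[20:60], 8); uniqB <- sample(ord[20:60], 8)
  sy <- pair_synergy(scores, mk(c(shared, uniqA)), mk(c(shared, uniqB)),
                     n_perm = 500, seed = 2)
  expect_lte(sy$p, 0.01)
  expect_gt(sy$nes, 0)
})

test_that("pair synergy p is roughly uniform when substrates are exchangeable", {
  set.seed(77)
  ps <- vapply(1:60, function(i) {
    scores <- stats::setNames(rnorm(80), sprintf("P%02d$1", 1:80))
    pool <- sample(names(scores), 24)
    shared <- pool[1:6]
    sA <- list(targets = data.frame(substrate = c(shared, pool[7:15]), sign = 1,
                                    weight = 1, stringsAsFactors = FALSE))
    sB <- list(targets = data.frame(substrate = c(shared, pool[16:24]), sign = 1,
                                    weight = 1, stringsAsFactors = FALSE))
    pair_synergy(scores, sA, sB, n_perm = 150, seed = i)$p
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the pviper object prints, summarizes and plots", {
  sim <- simulate_dataset(panel_cfg(81, spike_tks = "TK2",
                                    spike_samples = c("cell_001", "cell_002")))
  mr <- pviper(sim$matrix, truth_peptide_edges(sim),
               samples = c("cell_001", "cell_002"), pairs = "auto",
               n_perm = 300, seed = 4)
  expect_s3_class(mr, "pviper")
  expect_output(print(mr), "master-regulator")
  s <- summary(mr)
  expect_output(print(s), "Top regulator")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(mr))
  expect_true(all(mr$protein$q >= mr$protein$p - 1e-12))
})

test_that("the phosphosite rule reproduces the three sensitivity scenarios", {
  fit <- structure(list(
    peptide = data.frame(
      sample = rep(c("combo", "single", "insens"), each = 2),
      regulator = rep(c("EGFR$1197", "MET$1003"), 3),
      gene = rep(c("EGFR", "MET"), 3),
      nes = c(3, 2.5, 2.8, 0.2, -1.5, -2),
      p = c(0.001, 0.002, 0.004, 0.7, 0.3, 0.2),
      n_targets = 5, stringsAsFactors = FALSE),
    pairs = data.frame(
      sample = c("combo", "single", "insens"),
      a = "EGFR$1197",
      b = c("MET$1003", "OTHER$5", "MET$1003"),
      nes = c(3.1, 2.2, -0.5), p = c(0.01, 0.03, 0.8),
      n_shared = 4, stringsAsFactors = FALSE),
    params = list(alpha = 0.05)), class = "pviper")
  lab <- phosphosite_rule_classifier(fit)
  expect_equal(lab$label[lab$sample == "combo"], "combo_sensitive")
  expect_equal(lab$label[lab$sample == "single"], "single_agent")
  expect_equal(lab$label[lab$sample == "insens"], "insensitive")
  expect_false(attr(lab, "flagged"))

  flagged <- phosphosite_rule_classifier(fit, siteA = "ALK$1278")
  expect_true(attr(flagged, "flagged"))
})

test_that("a 14-line panel with two discordant lines feeds the Fisher example", {
  # 6 predicted-and-sensitive, 6 predicted-insensitive-and-resistant,
  # 2 false negatives: the prediction-vs-outcome table is [[6,0],[2,6]]
  predicted <- c(rep("combo_sensitive", 6), rep("insensitive", 8))
  observed <- c(rep("sensitive", 6), rep("sensitive", 2), rep("resistant", 6))
  tab <- table(factor(predicted == "combo_sensitive", c(TRUE, FALSE)),
               factor(observed == "sensitive", c(TRUE, FALSE)))
  expect_equal(unclass(unname(tab)), matrix(c(6, 2, 0, 6), 2),
               ignore_attr = TRUE)
  expect_equal(signif(fisher_exact_1sided(tab), 2), 0.0093)
})
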