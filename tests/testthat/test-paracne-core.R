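sim_small <- function(seed = 11, ...) {
  simulate_dataset(sim_config(n_tk = 5, n_substrates = 40, edges_per_tk = 5,
                              synergy_pairs = 0, n_tk_tk_edges = 0,
                              n_samples = c(tumor = 190, cell_line = 30,
                                            normal = 30), seed = seed, ...))
}

test_that("candidate inference recovers planted edges and excludes self-pairs", {
  sim <- sim_small()
  net <- infer_candidate_edges(sim$matrix, sim$kinases, M = 10)
  expect_gt(nrow(net), 0)
  expect_false(any(net$regulator == net$substrate))
  # every regulator is a kinase peptide
  reg_genes <- vapply(net$regulator,
                      function(id) parse_peptide_id(id, "dollar")$gene, "")
  expect_true(all(reg_genes %in% sim$kinases))
  r <- evaluate_recovery(aggregate_to_protein(apply_dpi(net, 0)), sim$truth)
  expect_gt(r$recall, 0.5)
  expect_gt(r$precision, 0.5)
})

test_that("independent rows yield (nearly) no candidate edges", {
  sim0 <- simulate_dataset(sim_config(n_tk = 5, n_substrates = 40,
                                      edges_per_tk = 5, synergy_pairs = 0,
                                      coupling_strength = 0,
                                      n_samples = c(tumor = 120, cell_line = 30,
                                                    normal = 30), seed = 13))
  net0 <- infer_candidate_edges(sim0$matrix, sim0$kinases, M = 10)
  # Bonferroni at alpha = 0.05 over all pairs: expected false edges < 1
  expect_lte(nrow(net0), 2)
})

test_that("a disjoint kinase list errors", {
  sim <- sim_small()
  expect_error(infer_candidate_edges(sim$matrix, c("AAA", "BBB"), M = 10),
               "kinase")
})

test_that("DPI removes the strictly weakest edge of a triangle", {
  tri <- data.frame(regulator = c("A$1", "B$1", "A$1"),
                    substrate = c("B$1", "C$1", "C$1"),
                    mi = c(0.9, 0.8, 0.3), stringsAsFactors = FALSE)
  out <- apply_dpi(tri, 0)
  expect_equal(nrow(out), 2)
  expect_false(any(out$mi == 0.3))

  # equal-MI weakest pair: strict inequality spares both
  tri2 <- tri; tri2$mi <- c(0.9, 0.8, 0.8)
  expect_equal(nrow(apply_dpi(tri2, 0)), 3)

  expect_error(apply_dpi(tri, 1), "tolerance")
  expect_error(apply_dpi(tri, -0.1), "tolerance")
})

test_that("DPI matches the exhaustive triangle-enumeration oracle", {
  for (s in 1:40) {
    net <- random_network(30, p_edge = 0.12, seed = 400 + s)
    for (tol in c(0, 0.1)) {
      got <- apply_dpi(net, tol)
      want <- dpi_oracle(net, tol)
      expect_identical(got[order(got$regulator, got$substrate), ],
                       want[order(want$regulator, want$substrate), ],
                       info = sprintf("seed %d tol %.1f", 400 + s, tol))
    }
  }
})

test_that("DPI removals are always a violating triangle's strict weakest edge", {
  for (s in 1:10) {
    net <- random_network(20, p_edge = 0.2, seed = 500 + s)
    out <- apply_dpi(net, 0)
    expect_lte(nrow(out), nrow(net))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    kept <- key(out$regulator, out$substrate)
    w <- stats::setNames(net$mi, key(net$regulator, net$substrate))
    removed <- setdiff(names(w), kept)
    # collect, per edge, whether some triangle marks it as strict weakest
    weakest_somewhere <- character()
    cmb <- utils::combn(unique(c(net$regulator, net$substrate)), 3)
    for (t in seq_len(ncol(cmb))) {
      ks <- c(key(cmb[1, t], cmb[2, t]), key(cmb[1, t], cmb[3, t]),
              key(cmb[2, t], cmb[3, t]))
      if (!all(ks %in% names(w))) next
      wi <- w[ks]
      lo <- which.min(wi)
      if (wi[lo] < min(wi[-lo]))
        weakest_somewhere <- c(weakest_somewhere, ks[lo])
    }
    expect_true(all(removed %in% weakest_somewhere))
    # a triangle's unique maximum is never the edge that triangle removes:
    # an edge removed despite being some triangle's unique max must be the
    # weakest of a different triangle
    expect_true(all(vapply(removed, function(e)
      sum(weakest_somewhere == e) >= 1, TRUE)))
  }
})

test_that("bootstrap consolidation is deterministic and sparsifying", {
  sim <- sim_small()
  net1 <- bootstrap_consolidate(sim$matrix, sim$kinases, B = 10, seed = 7)
  net2 <- bootstrap_consolidate(sim$matrix, sim$kinases, B = 10, seed = 7)
  expect_identical(net1, net2)
  expect_true(all(net1$support <= 10))
  expect_gt(nrow(net1), 0)
  # strongly planted edges persist across (essentially all) bootstraps
  expect_gt(max(net1$support), 8)
  expect_error(bootstrap_consolidate(sim$matrix, sim$kinases, B = 1), "B")
})

test_that("poorly supported edges are dropped by the Poisson consolidation", {
  sim <- sim_small()
  poisson_net <- bootstrap_consolidate(sim$matrix, sim$kinases, B = 12, seed = 3,
                                       consolidate = "poisson")
  # the Poisson rule keeps only edges whose support clears the Bonferroni
  # tail of a Poisson at the mean support; singleton-support edges cannot
  lambda_ub <- max(poisson_net$support)  # support ceiling sanity
  expect_true(all(poisson_net$support > 1))
  maj <- bootstrap_consolidate(sim$matrix, sim$kinases, B = 12, seed = 3,
                               consolidate = "majority")
  expect_true(all(maj$support > 6))
})

test_that("Spearman annotation flags degenerate rows and finds closed forms", {
  counts <- rbind(
    "K$1" = c(5L, 4L, 3L, 2L, 1L, 0L),
    "A$1" = c(0L, 1L, 2L, 3L, 4L, 5L),  # perfect rank reversal of K
    "B$1" = c(2L, 2L, 2L, 2L, 2L, 2L))  # constant: rho undefined
  colnames(counts) <- paste0("s", 1:6)
  m <- count_matrix(counts)
  net <- data.frame(regulator = c("K$1", "K$1"), substrate = c("A$1", "B$1"),
                    mi = c(0.5, 0.4), stringsAsFactors = FALSE)
  ann <- annotate_spearman(net, m)
  expect_equal(ann$rho[1], -1)
  expect_false(ann$rho_defined[2])
  rep <- negative_rho_report(ann)
  expect_equal(rep$n_edges, 1)       # constant row excluded from denominator
  expect_equal(rep$n_negative, 1)

  bad <- data.frame(regulator = "K$1", substrate = "MISSING$9", mi = 1)
  expect_error(annotate_spearman(bad, m), "MISSING")
})

test_that("protein aggregation keeps the maximum MI and is idempotent", {
  net <- data.frame(regulator = c("EGFR$1197", "EGFR$1069", "MET$1003"),
                    substrate = c("X$5", "X$12", "Y$7"),
                    mi = c(0.4, 0.7, 0.2), stringsAsFactors = FALSE)
  pn <- aggregate_to_protein(net)
  expect_equal(nrow(pn), 2)
  expect_equal(pn$mi[pn$regulator == "EGFR"], 0.7)
  expect_equal(pn$n_peptide_edges[pn$regulator == "EGFR"], 2L)

  one <- aggregate_to_protein(net[3, ])
  expect_equal(one$mi, 0.2)

  # idempotent on protein-unique networks (ids need a site to parse)
  pn_as_pep <- data.frame(regulator = paste0(pn$regulator, "$1"),
                          substrate = paste0(pn$substrate, "$1"),
                          mi = pn$mi, stringsAsFactors = FALSE)
  pn2 <- aggregate_to_protein(pn_as_pep)
  expect_equal(pn2$mi, pn$mi)
  expect_equal(pn2$regulator, pn$regulator)

  expect_error(aggregate_to_protein(net[0, ]), "empty")
})

test_that("TK-TK bias test behaves at both extremes", {
  kin <- paste0("TK", 1:10)
  all_tk <- data.frame(regulator = rep(kin[1:5], each = 4),
                       substrate = rep(kin[6:9], 5), mi = 1)
  universe <- c(kin, paste0("SUB", 1:90))
  expect_lt(tk_tk_bias_test(all_tk, kin, universe)$p, 1e-10)

  none_tk <- data.frame(regulator = rep(kin[1:5], each = 4),
                        substrate = paste0("SUB", 1:20), mi = 1)
  expect_gt(tk_tk_bias_test(none_tk, kin, universe)$p, 0.9)
})

test_that("TK-TK bias p is roughly uniform when targets are drawn uniformly", {
  set.seed(61)
  kin <- paste0("TK", 1:10)
  universe <- c(kin, paste0("SUB", 1:40))
  ps <- vapply(1:200, function(i) {
    pn <- data.frame(regulator = sample(kin, 15, replace = TRUE),
                     substrate = sample(universe, 15, replace = TRUE), mi = 1)
    tk_tk_bias_test(pn, kin, universe)$p
  }, 0)
  # discrete p-values: check both tails are populated sensibly
  expect_gt(mean(ps), 0.35)
  expect_gt(mean(ps <= 0.2), 0.05)
})

test_that("the paracne fit object carries methods and a coherent summary", {
  sim <- sim_small()
  fit <- paracne(sim$matrix, sim$kinases, B = 8, seed = 2)
  expect_s3_class(fit, "paracne")
  expect_output(print(fit), "peptide-level edges")
  s <- summary(fit)
  expect_s3_class(s, "summary.paracne")
  expect_output(print(s), "protein edges")
  expect_equal(s$n_peptide_edges, nrow(fit$network))
  expect_true(all(c("rho", "rho_p", "support") %in% names(fit$network)))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
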