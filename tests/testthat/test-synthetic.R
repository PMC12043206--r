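test_that("generator output is bit-stable under seed and validates specs", {
  spec <- synthetic_spec(seed = 42, n_ecotypes = 2, n_taxa = 50)
  g1 <- generate_community(spec)
  g2 <- generate_community(spec)
  expect_identical(unclass(g1$counts), unclass(g2$counts))
  expect_identical(g1$truth$taxa, g2$truth$taxa)

  expect_error(synthetic_spec(n_taxa = 5), "rank out of range")
  expect_error(synthetic_spec(
    planted_effects = data.frame(rank = c(11, 11), fold = 3,
                                 n_ecotypes_affected = 2)), "disjoint")
  expect_error(synthetic_spec(
    network_modules = data.frame(rank_from = 21, rank_to = 25,
                                 lambda = 1.4)), "lambda")
})

test_that("null generator means track the base profile", {
  # seed-averaged mean relative abundance of each of the 30 most abundant
  # taxa stays within 3 standard errors of the planted base profile
  seeds <- 1:20
  means <- sapply(seeds, function(sd) {
    g <- generate_community(null_synthetic_spec(seed = sd, n_ecotypes = 2,
                                                n_taxa = 100))
    colMeans(to_relative_abundance(g$counts))[1:30]
  })
  # the base profile differs per seed; compare each seed's mean to its own
  bases <- sapply(seeds, function(sd) {
    generate_community(null_synthetic_spec(
      seed = sd, n_ecotypes = 2, n_taxa = 100))$truth$taxa$base_abundance[1:30]
  })
  dev <- rowMeans(means - bases)
  se <- apply(means - bases, 1L, stats::sd) / sqrt(length(seeds))
  # per-taxon 3-SE bands; allow the expected handful of tail misses over
  # 30 simultaneous bands, with a hard 5-SE cap on every taxon
  expect_gte(mean(abs(dev) <= 3 * se + 1e-12), 0.9)
  expect_true(all(abs(dev) <= 5 * se + 1e-12))
})

test_that("fold-1 planting equals the null spec draw for draw", {
  # group_differential must also be 1: it multiplies planted folds in
  # tolerant-class ecotypes, so any value != 1 is itself an effect
  eff <- data.frame(rank = 11:14, fold = 1, n_ecotypes_affected = 4)
  g_eff <- generate_community(synthetic_spec(seed = 3, n_ecotypes = 4,
                                             n_taxa = 50,
                                             planted_effects = eff,
                                             group_differential = 1,
                                             network_modules = NULL))
  g_null <- generate_community(null_synthetic_spec(seed = 3, n_ecotypes = 4,
                                                   n_taxa = 50))
  expect_identical(unclass(g_eff$counts), unclass(g_null$counts))
})

test_that("module planting raises within-module Spearman correlation", {
  diffs <- sapply(1:5, function(sd) {
    g <- generate_community(synthetic_spec(
      seed = sd, n_ecotypes = 2, n_reps = 10, n_taxa = 60,
      planted_effects = NULL,
      network_modules = data.frame(rank_from = 21, rank_to = 28,
                                   lambda = 0.9)))
    ra <- unclass(to_relative_abundance(g$counts))
    rho <- stats::cor(ra[, 15:35], method = "spearman")
    in_mod <- colnames(rho) %in% sprintf("ASV%04d", 21:28)
    within <- rho[in_mod, in_mod][upper.tri(diag(sum(in_mod)))]
    between <- rho[in_mod, !in_mod]
    mean(within) - mean(between)
  })
  expect_gt(mean(diffs), 0.3)
})

test_that("sequence divergence maps to analytic identity", {
  sq0 <- generate_sequences(30L, n_isolates = 10, divergence = 0,
                            seed = 11)
  expect_identical(unname(sq0$isolates),
                   unname(sq0$asv[sq0$pairing$source_asv]))
  sq1 <- generate_sequences(30L, n_isolates = 15, divergence = 0.01,
                            seed = 12)
  # expected identity 0.99, binomial SE sqrt(p(1-p)/L) per isolate
  se <- sqrt(0.01 * 0.99 / 420)
  expect_lt(abs(mean(sq1$pairing$true_identity) - 0.99), 2 * se)
  obs <- pairwise_identity(sq1$asv[[sq1$pairing$source_asv[1]]],
                           sq1$isolates[[1]])
  expect_equal(obs, sq1$pairing$true_identity[1], tolerance = 1e-12)
  sq5 <- generate_sequences(30L, n_isolates = 15, divergence = 0.05,
                            seed = 13)
  expect_lt(mean(sq5$pairing$true_identity), 0.97)
  expect_error(generate_sequences(30L, 5, divergence = 0.5), "divergence")
  expect_error(generate_sequences(10L, 11), "exceeds")
})

test_that("phenotypes recover the planted tolerance ranking", {
  hits <- sapply(1:10, function(sd) {
    g <- generate_community(synthetic_spec(seed = sd, n_taxa = 30,
                                           planted_effects = NULL,
                                           network_modules = NULL))
    ph <- generate_phenotypes(g$truth, seed = sd)
    rk <- rank_tolerance(ph, k = 5)
    tol <- g$truth$ecotypes$ecotype[
      g$truth$ecotypes$tolerance_class == "tolerant"]
    mean(rk$tolerant %in% tol)
  })
  expect_gte(mean(hits), 0.9)

  # zero noise: weights deterministic, drought RFW equals the truth factor
  g <- generate_community(synthetic_spec(seed = 2, n_taxa = 30,
                                         planted_effects = NULL,
                                         network_modules = NULL))
  ph0 <- generate_phenotypes(g$truth, cv = 0, seed = 1)
  rfw <- relative_fresh_weight(ph0, "Eco01", "live")
  expect_equal(unname(rfw),
               rep(g$truth$ecotypes$rfw_live[1], length(rfw)),
               tolerance = 1e-12)
})
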