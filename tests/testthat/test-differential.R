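test_that("wilcoxon_rank_sum reproduces the exact enumeration", {
  # fully separated 4v4: the two extreme assignments out of C(8,4) = 70
  expect_equal(wilcoxon_rank_sum(1:4, 5:8), 2 / 70)
  expect_equal(wilcoxon_rank_sum(c(3, 3, 3), c(3, 3, 3)), 1)
  # same multiset split across groups
  expect_equal(wilcoxon_rank_sum(c(1, 2, 5), c(5, 1, 2)), 1)
})

test_that("wilcoxon_rank_sum equals the brute-force oracle with and
           without ties", {
  set.seed(101)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:8, n1, replace = TRUE)  # small support forces ties
    y <- sample(1:8, n2, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y), oracle_ranksum_p(x, y),
                 info = sprintf("x=%s y=%s", toString(x), toString(y)))
  }
  # untied values against R's exact test
  for (i in 1:20) {
    x <- sample(1:100, 5); y <- sample(101:200, 4) - sample(0:120, 4)
    if (length(unique(c(x, y))) < 9) next
    expect_equal(wilcoxon_rank_sum(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large-sample path approximates the exact test", {
  set.seed(7)
  x <- rnorm(15); y <- rnorm(15, 1)
  p_norm <- wilcoxon_rank_sum(x, y)
  p_ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_norm, p_ref, tolerance = 1e-9)
})

test_that("welch_t_test matches the textbook computation", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4)
  ref <- stats::t.test(x, y)$p.value
  expect_equal(welch_t_test(x, y), ref, tolerance = 1e-12)
  expect_equal(welch_t_test(x, y), welch_t_test(y, x))
  expect_equal(welch_t_test(c(-2, -1, 1, 2), c(-2, -1, 1, 2)), 1)
  expect_equal(welch_t_test(c(1, 1), c(1, 1)), 1)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("bh_adjust equals the step-up oracle and p.adjust", {
  set.seed(33)
  for (i in 1:30) {
    p <- round(runif(sample(1:20, 1)), 3)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("fold_change handles the degenerate conventions", {
  ra <- make_relab(matrix(c(2, 2, 0, 1,
                            2, 2, 0, 3,
                            4, 2, 0, 1,
                            4, 2, 0, 3), 4, 4, byrow = TRUE,
                          dimnames = list(c("c1", "c2", "d1", "d2"),
                                          c("t1", "t2", "t3", "t4"))))
  expect_gt(fold_change(ra, "t1", c("d1", "d2"), c("c1", "c2")), 1)
  expect_equal(fold_change(ra, "t3", c("d1", "d2"), c("c1", "c2")), 1)
  expect_error(fold_change(ra, "t1", character(0), c("c1", "c2")),
               "non-empty")
})

test_that("per_ecotype_da applies the abundance filter before testing", {
  g <- generate_community(synthetic_spec(seed = 4,
                                         depth_range = c(10000L, 10000L)))
  ra <- to_relative_abundance(g$counts)
  da <- per_ecotype_da(ra, g$design, "Eco01", abundance_min = 0.001)
  des <- as.data.frame(g$design)
  eco_samples <- des$sample_id[des$ecotype == "Eco01"]
  means <- colMeans(unclass(ra)[eco_samples, ])
  expect_true(all(means[da$taxon] > 0.001))
  expect_true(all(!(names(means)[means <= 0.001] %in% da$taxon)))
  expect_true(all(da$fold > 0))
  expect_true(all(da$direction[da$fold > 1] == "enriched"))
  expect_error(per_ecotype_da(ra, g$design, "EcoXX"), "replicates")
})

# hand-built DA tables: taxon "hit" enriched in 6/10 ecotypes, "weak" in
# 4/10, "low" enriched but below the fold threshold everywhere
fake_da <- function() {
  lapply(sprintf("E%02d", 1:10), function(e) {
    i <- as.integer(sub("E", "", e))
    structure(data.frame(
      ecotype = e,
      taxon = c("hit", "weak", "low"),
      mean_control = 0.01, mean_drought = 0.02,
      p = c(if (i <= 6) 0.01 else 0.5, if (i <= 4) 0.01 else 0.5, 0.01),
      p_adjusted = NA_real_,
      fold = c(1.5, 1.5, 1.1),
      direction = "enriched",
      da = c(i <= 6, i <= 4, TRUE), stringsAsFactors = FALSE),
      class = c("da_result", "data.frame"))
  })
}

test_that("call_core_responsive applies the k_core and fold rules", {
  cc <- as.data.frame(call_core_responsive(fake_da(), k_core = 5,
                                           f_min = 1.2))
  expect_identical(cc$status[cc$taxon == "hit"], "core_enriched")
  expect_identical(cc$status[cc$taxon == "weak"], "none")   # 4 < k_core
  expect_identical(cc$status[cc$taxon == "low"], "none")    # fold < 1.2
  expect_identical(cc$n_ecotypes_enriched[cc$taxon == "hit"], 6L)
  expect_error(call_core_responsive(fake_da()[1:3]), "k_core")
})

test_that("core calling is monotone in added ecotype support", {
  da <- fake_da()
  cc0 <- as.data.frame(call_core_responsive(da))
  # grant "weak" one more supporting ecotype at a time; once core, adding
  # support never revokes the call
  statuses <- character(0)
  for (extra in 5:10) {
    da2 <- lapply(da, function(d) {
      i <- as.integer(sub("E", "", d$ecotype[1]))
      if (i <= extra) {
        d$p[d$taxon == "weak"] <- 0.01
        d$da[d$taxon == "weak"] <- TRUE
      }
      d
    })
    cc <- as.data.frame(call_core_responsive(da2))
    statuses <- c(statuses, cc$status[cc$taxon == "weak"])
  }
  expect_identical(statuses, rep("core_enriched", 6))
  expect_identical(cc0$status[cc0$taxon == "hit"], "core_enriched")
})

test_that("group_fold_contrast labels and breaks ties deterministically", {
  da <- fake_da()
  cc <- call_core_responsive(da)
  des <- study_design(data.frame(
    sample_id = sprintf("s%02d", 1:20),
    ecotype = rep(sprintf("E%02d", 1:10), each = 2),
    treatment = rep(c("control", "drought"), 10),
    tolerance_class = rep(c("tolerant", "sensitive"), each = 10),
    replicate = 1L))
  gc <- group_fold_contrast(cc, des)
  # folds identical in every ecotype -> tie labelled "equal"
  expect_identical(gc$group_contrast[gc$taxon == "hit"], "equal")

  fm <- attr(cc, "fold_matrix")
  fm["hit", sprintf("E%02d", 1:5)] <- 3
  attr(cc, "fold_matrix") <- fm
  gc2 <- group_fold_contrast(cc, des)
  expect_identical(gc2$group_contrast[gc2$taxon == "hit"],
                   "higher_in_tolerant")
})
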