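test_that("alpha diversity matches hand computations", {
  ct <- count_table(matrix(c(10L, 0L, 0L,
                             5L, 5L, 5L,
                             3L, 1L, 0L), 3, 3, byrow = TRUE,
                           dimnames = list(c("s1", "s2", "s3"),
                                           c("a", "b", "c"))))
  ad <- alpha_diversity(ct)
  expect_equal(ad$shannon, c(0, log(3),
                             -(0.75 * log(0.75) + 0.25 * log(0.25))))
  expect_identical(ad$richness, c(1L, 3L, 2L))
})

test_that("bray_curtis matches hand values and vegan on random tables", {
  ra <- make_relab(matrix(c(0.5, 0.5, 0,
                            0.25, 0.25, 0.5,
                            0, 0, 1), 3, 3, byrow = TRUE,
                          dimnames = list(c("s1", "s2", "s3"), NULL)))
  d <- bray_curtis(ra)
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(d["s1", "s3"], 1)        # disjoint supports
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(d, t(d))

  skip_if_not_installed("vegan")
  set.seed(8)
  m <- make_relab(matrix(rexp(10 * 20), 10, 20,
                         dimnames = list(paste0("s", 1:10), NULL)))
  expect_equal(unname(bray_curtis(m)),
               unname(as.matrix(vegan::vegdist(unclass(m), "bray"))),
               tolerance = 1e-12)
})

test_that("pcoa recovers Euclidean configurations", {
  # collinear points: one positive axis carries all inertia
  y <- c(0, 1, 3, 7)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  p <- pcoa(d)
  expect_equal(p$explained[1], 1)
  expect_equal(as.matrix(dist(p$coordinates[, 1])), unname(d),
               ignore_attr = TRUE)

  # equilateral triangle: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(d3)
  ev <- p3$eigenvalues[p3$eigenvalues > 1e-9]
  expect_equal(ev[1], ev[2])

  # general Euclidean reconstruction
  set.seed(4)
  x <- matrix(rnorm(18), 6, 3, dimnames = list(paste0("s", 1:6), NULL))
  dd <- as.matrix(dist(x))
  pr <- pcoa(dd)
  expect_equal(as.matrix(dist(pr$coordinates)), dd, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcoa(dd[1:2, 1:2]), "at least 3")
})

test_that("permanova equals classical ANOVA on 1-D Euclidean data", {
  set.seed(12)
  for (rep in 1:5) {
    y <- rnorm(15)
    gl <- sample(rep(c("a", "b", "c"), each = 5))
    d <- as.matrix(dist(y))
    dimnames(d) <- list(sprintf("s%02d", 1:15), sprintf("s%02d", 1:15))
    f_cl <- stats::anova(stats::lm(y ~ gl))$`F value`[1]
    expect_equal(permanova(d, gl, n_perm = 9, seed = rep)$pseudo_F, f_cl,
                 tolerance = 1e-9)
  }
})

test_that("permanova detects planted shifts and guards bad groupings", {
  set.seed(5)
  base <- matrix(rexp(16 * 30), 16, 30,
                 dimnames = list(sprintf("s%02d", 1:16), NULL))
  gl <- rep(c("a", "b"), each = 8)
  shifted <- base
  shifted[gl == "b", 1:5] <- shifted[gl == "b", 1:5] * 6
  r_null <- permanova(bray_curtis(make_relab(base)), gl, n_perm = 199,
                      seed = 1)
  r_alt <- permanova(bray_curtis(make_relab(shifted)), gl, n_perm = 199,
                     seed = 1)
  expect_gt(r_alt$R2, r_null$R2)
  expect_lte(r_alt$p, 0.05)
  expect_true(r_alt$R2 >= 0 && r_alt$R2 <= 1)

  d <- bray_curtis(make_relab(base))
  expect_error(permanova(d, rep("a", 16)), "two groups")
  expect_error(permanova(d, c("b", rep("a", 15))), "at least 2 samples")
})

test_that("sequential two-factor partitioning matches adonis2 by terms", {
  skip_if_not_installed("vegan")
  g <- generate_community(synthetic_spec(seed = 6, n_ecotypes = 4,
                                         n_taxa = 60))
  ra <- to_relative_abundance(g$counts)
  d <- bray_curtis(ra)
  des <- as.data.frame(g$design)
  res <- permanova_sequential(d, des$ecotype, des$treatment,
                              n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ ecotype + treatment,
                        data = des, permutations = 99, by = "terms")
  expect_equal(res$R2, ref$R2[1:2], tolerance = 1e-8)
  expect_equal(res$pseudo_F, ref$F[1:2], tolerance = 1e-8)
})

test_that("cumulative_abundance sums and averages correctly", {
  ra <- make_relab(matrix(c(0.1, 0.05, 0.85,
                            0.1, 0.05, 0.85), 2, 3, byrow = TRUE,
                          dimnames = list(c("s1", "s2"),
                                          c("a", "b", "c"))))
  expect_equal(cumulative_abundance(ra, c("a", "b")), 0.15)
  expect_equal(cumulative_abundance(ra, c("a", "b", "c")), 1)
  expect_warning(z <- cumulative_abundance(ra, character(0)), "empty")
  expect_equal(z, 0)
  expect_error(cumulative_abundance(ra, "nope"), "not in table")
})
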