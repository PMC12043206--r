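# hand-built 6-node toy pair; expected NESH (case-specific-neighbor
# fraction |B\A|/|B|) from set arithmetic:
#   control: a-b, a-c, b-c, d-e          case: a-b, a-d, d-e, e-f, c-f
#   A(a)={b,c} B(a)={b,d}  -> |{d}|/|{b,d}| = 1/2
#   A(b)={a,c} B(b)={a}    -> 0/1 = 0
#   A(c)={a,b} B(c)={f}    -> 1/1 = 1
#   A(d)={e}   B(d)={a,e}  -> 1/2
#   A(e)={d}   B(e)={d,f}  -> 1/2
#   A(f)={}    B(f)={e,c}  -> 2/2 = 1
toy_pair <- function() {
  nodes <- letters[1:6]
  ctl <- make_net(nodes, list(c("a", "b"), c("a", "c"), c("b", "c"),
                              c("d", "e")))
  cas <- make_net(nodes, list(c("a", "b"), c("a", "d"), c("d", "e"),
                              c("e", "f"), c("c", "f")))
  list(ctl = ctl, cas = cas)
}

test_that("nesh_scores matches the set-arithmetic oracle on the toy pair", {
  tp <- toy_pair()
  rep <- nesh_scores(tp$ctl, tp$cas)
  s <- rep$scores
  expect_equal(stats::setNames(s$nesh, s$node),
               c(a = 1 / 2, b = 0, c = 1, d = 1 / 2, e = 1 / 2, f = 1))
  expect_equal(range(s$nesh_scaled), c(0, 1))
  expect_equal(s$nesh_scaled, (s$nesh - 0) / 1)
  cls <- stats::setNames(rep$edges$class,
                         paste(rep$edges$i, rep$edges$j))
  expect_identical(cls[["a b"]], "shared")
  expect_identical(cls[["b c"]], "control_only")
  expect_identical(cls[["c f"]], "case_only")
})

test_that("identical networks give zero NESH and no drivers", {
  tp <- toy_pair()
  rep <- identify_drivers(nesh_scores(tp$ctl, tp$ctl))
  expect_true(all(rep$scores$nesh == 0))
  expect_true(all(rep$scores$nesh_scaled == 0))
  expect_identical(rep$drivers, character(0))
  expect_true(all(rep$edges$class == "shared"))
})

test_that("full neighborhood turnover scores 1 and can drive", {
  nodes <- c("hub", "x", "y", "z")
  ctl <- make_net(nodes, list(c("hub", "x")))
  cas <- make_net(nodes, list(c("hub", "y"), c("hub", "z"), c("x", "y")))
  rep <- identify_drivers(nesh_scores(ctl, cas))
  s <- rep$scores
  expect_equal(s$nesh[s$node == "hub"], 1)
  expect_true("hub" %in% rep$drivers)
})

test_that("swapping control and case gives the complement scores", {
  set.seed(17)
  for (i in 1:10) {
    nodes <- paste0("n", 1:8)
    pairs <- combn(nodes, 2, simplify = FALSE)
    ctl <- make_net(nodes, pairs[runif(length(pairs)) < 0.35])
    cas <- make_net(nodes, pairs[runif(length(pairs)) < 0.35])
    fwd <- nesh_scores(ctl, cas)$scores
    rev <- nesh_scores(cas, ctl)$scores
    expect_true(all(fwd$nesh >= 0 & fwd$nesh <= 1))
    # swapping control and case yields the control-specific fraction
    nb <- function(net) {
      adj <- stats::setNames(vector("list", 8), nodes)
      for (k in seq_len(nrow(net$edges))) {
        adj[[net$edges$i[k]]] <- c(adj[[net$edges$i[k]]], net$edges$j[k])
        adj[[net$edges$j[k]]] <- c(adj[[net$edges$j[k]]], net$edges$i[k])
      }
      adj
    }
    A <- nb(ctl); B <- nb(cas)
    for (v in nodes) {
      if (length(A[[v]]) == 0) next
      expect_equal(rev$nesh[rev$node == v],
                   length(setdiff(A[[v]], B[[v]])) / length(A[[v]]))
    }
    # node relabelling leaves driver calls invariant
    map <- stats::setNames(paste0("m", 1:8), nodes)
    relab <- function(net) {
      e <- net$edges
      ij <- Map(function(a, b) c(map[[a]], map[[b]]), e$i, e$j)
      make_net(unname(map[net$nodes]), unname(ij))
    }
    d1 <- identify_drivers(nesh_scores(ctl, cas))$drivers
    d2 <- identify_drivers(nesh_scores(relab(ctl), relab(cas)))$drivers
    expect_setequal(unname(map[d1]), d2)
  }
})

test_that("core_drivers aggregates to genus with the >= min_ecotypes rule", {
  tax <- taxonomy_table(data.frame(
    taxon_id = paste0("t", 1:4),
    kingdom = "Bacteria", phylum = "P", class = "C", order = "O",
    family = c("F1", "F1", "F2", "F2"),
    genus = c("Massilia", "Massilia", NA, "Streptomyces"),
    stringsAsFactors = FALSE))
  mk_rep <- function(drivers) {
    r <- nesh_scores(make_net(paste0("t", 1:4), list(c("t1", "t2"))),
                     make_net(paste0("t", 1:4), list(c("t1", "t3"))))
    r$drivers <- drivers
    r
  }
  reports <- stats::setNames(lapply(1:10, function(i) {
    mk_rep(c(if (i <= 4) "t1", if (i <= 3) "t4", if (i <= 2) "t3"))
  }), sprintf("E%02d", 1:10))
  cd <- core_drivers(reports, tax, min_ecotypes = 4)
  expect_identical(cd$core_genera, "Massilia")      # 4/10 makes the cut
  tab <- cd$table
  expect_identical(tab$n_ecotypes[tab$genus == "Streptomyces"], 3L)
  expect_false(tab$core[tab$genus == "Streptomyces"])
  expect_identical(tab$genus[1], "Massilia")        # ranked by support
  # bulk overlap bookkeeping
  cd2 <- core_drivers(reports, tax, min_ecotypes = 4,
                      bulk_report = mk_rep("t4"))
  expect_identical(cd2$bulk_overlap$shared, "Streptomyces")
  expect_true("Massilia" %in% cd2$bulk_overlap$root_only)
})
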