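# cache of exact rank-sum null distributions, keyed by "n1,n2"
.ranksum_cache <- new.env(parent = emptyenv())

# exhaustive distribution of the rank-sum of group 1 over all C(n,n1)
# assignments of the pooled (tied or untied) values
.ranksum_null <- function(pooled_ranks, n1) {
  key <- paste(c(n1, signif(sort(pooled_ranks), 12)), collapse = ",")
  if (!is.null(.ranksum_cache[[key]])) return(.ranksum_cache[[key]])
  combos <- utils::combn(length(pooled_ranks), n1)
  sums <- colSums(matrix(pooled_ranks[combos], nrow = n1))
  .ranksum_cache[[key]] <- sums
  sums
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact by enumeration of all C(n1+n2, n1) group assignments whenever
#' n1 + n2 <= `exact_max` (enumeration of the actual mid-ranks, so ties are
#' handled exactly too); otherwise the tie-corrected normal approximation
#' with continuity correction. Two-sided p is
#' P(|W - E W| >= |W_obs - E W|) under the enumerated null.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param exact_max largest pooled size for exact enumeration.
#' @return p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  if (length(unique(c(x, y))) == 1) return(1)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  if (n1 + n2 <= exact_max) {
    null <- .ranksum_null(r, n1)
    dev <- abs(null - mu)
    p <- mean(dev >= abs(w_obs - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      (n1 + n2 + 1 - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(z, 0))
  }
  min(p, 1)
}

#' Two-sided Welch t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' Degenerate inputs (zero variance in both groups) return p = 1 for equal
#' means and p = 0-adjacent via the limit otherwise is an error.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return p-value.
#' @export
welch_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (mean(x) == mean(y)) return(1)
    stop("zero variance in both groups with unequal means")
  }
  se2 <- v1 / n1 + v2 / n2
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(tt), df)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values.
#' @return adjusted p-values (monotone step-up, capped at 1), in the input
#'   order.
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq(n, 1) * p[o]))[ro]
}

#' Drought/control fold change of one taxon
#'
#' Ratio of group-mean relative abundances with a symmetric pseudocount
#' guarding zeros: (mean_a + eps) / (mean_b + eps). Two all-zero groups
#' give fold 1 by convention.
#'
#' @param t a `relative_abundance` matrix (or [count_table()]).
#' @param taxon taxon id.
#' @param samples_a,samples_b sample ids of the numerator (drought) and
#'   denominator (control) groups.
#' @param eps pseudocount on the relative-abundance scale.
#' @export
fold_change <- function(t, taxon, samples_a, samples_b, eps = 1e-6) {
  if (is_count_table(t)) t <- to_relative_abundance(t)
  if (length(samples_a) == 0 || length(samples_b) == 0)
    stop("both groups must be non-empty")
  m <- unclass(t)
  (mean(m[samples_a, taxon]) + eps) / (mean(m[samples_b, taxon]) + eps)
}

#' Per-ecotype differential abundance (drought vs control)
#'
#' Reproduces the per-genotype screening procedure: taxa with overall mean
#' relative abundance above `abundance_min` (default 0.1%) within the
#' ecotype's samples are tested drought vs control with the two-sided
#' Wilcoxon rank-sum test; a taxon is DA when p < `alpha`, with direction
#' taken from the drought/control fold. No multiplicity adjustment by
#' default (`adjust = "BH"` switches the call criterion to adjusted p).
#'
#' @param t a [count_table()] or `relative_abundance` matrix.
#' @param design a [study_design()].
#' @param ecotype ecotype name.
#' @param abundance_min minimum overall mean relative abundance.
#' @param alpha significance threshold.
#' @param adjust `"none"` (default, mirrors the screening criterion) or
#'   `"BH"`.
#' @param eps pseudocount passed to [fold_change()].
#' @return data.frame of class `da_result`: ecotype, taxon, mean relative
#'   abundance per treatment, p (and p_adjusted), fold, direction, da flag.
#' @export
per_ecotype_da <- function(t, design, ecotype, abundance_min = 0.001,
                           alpha = 0.05, adjust = c("none", "BH"),
                           eps = 1e-6) {
  adjust <- match.arg(adjust)
  if (is_count_table(t)) t <- to_relative_abundance(t)
  m <- unclass(t)
  des <- as.data.frame(design)
  des <- des[des$ecotype == ecotype & des$sample_id %in% rownames(m), ]
  s_d <- des$sample_id[des$treatment == "drought"]
  s_c <- des$sample_id[des$treatment == "control"]
  if (length(s_d) < 2 || length(s_c) < 2)
    stop("ecotype '", ecotype, "' needs >= 2 replicates in both treatments")
  sub <- m[c(s_c, s_d), , drop = FALSE]
  keep <- colnames(sub)[colMeans(sub) > abundance_min]
  if (length(keep) == 0)
    return(structure(data.frame(), class = c("da_result", "data.frame")))
  p <- vapply(keep, function(tx)
    wilcoxon_rank_sum(m[s_d, tx], m[s_c, tx]), numeric(1))
  fold <- vapply(keep, function(tx)
    fold_change(t, tx, s_d, s_c, eps = eps), numeric(1))
  p_adj <- bh_adjust(p)
  p_call <- if (adjust == "BH") p_adj else p
  out <- data.frame(
    ecotype = ecotype, taxon = keep,
    mean_control = colMeans(m[s_c, keep, drop = FALSE]),
    mean_drought = colMeans(m[s_d, keep, drop = FALSE]),
    p = p, p_adjusted = p_adj, fold = fold,
    direction = ifelse(fold > 1, "enriched",
                       ifelse(fold < 1, "depleted", "none")),
    da = p_call < alpha, row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("da_result", "data.frame"))
}

#' Cross-ecotype core-responsive taxon calling
#'
#' A taxon is `core_enriched` when it is DA with direction enriched and
#' fold >= `f_min` in at least `k_core` ecotypes; `core_depleted` is the
#' symmetric rule with fold <= 1/`f_min`. A taxon reaching `k_core` in both
#' directions (possible only in pathological inputs) is flagged
#' `ambiguous`. The cluster direction (enrichment vs depletion cluster) is
#' assigned by the majority DA direction across ecotypes.
#'
#' @param da_list list of `da_result` data.frames, one per ecotype
#'   (bulk-soil pseudo-ecotypes should be excluded by the caller).
#' @param k_core minimum number of supporting ecotypes.
#' @param f_min enrichment fold threshold (>= 1).
#' @return data.frame of class `core_call`: taxon, n_ecotypes_enriched,
#'   n_ecotypes_depleted, status, cluster, plus the per-ecotype fold matrix
#'   in `attr(, "fold_matrix")` (taxa x ecotypes, NA where untested).
#' @export
call_core_responsive <- function(da_list, k_core = 5, f_min = 1.2) {
  da <- do.call(rbind, lapply(da_list, as.data.frame))
  if (is.null(da) || nrow(da) == 0)
    return(structure(data.frame(), class = c("core_call", "data.frame")))
  ecos <- unique(da$ecotype)
  if (length(ecos) < k_core)
    stop("need at least k_core = ", k_core, " ecotypes, got ", length(ecos))
  taxa <- sort(unique(da$taxon))
  fold_m <- matrix(NA_real_, length(taxa), length(ecos),
                   dimnames = list(taxa, ecos))
  fold_m[cbind(match(da$taxon, taxa), match(da$ecotype, ecos))] <- da$fold
  enr <- da$da & da$direction == "enriched" & da$fold >= f_min
  dep <- da$da & da$direction == "depleted" & da$fold <= 1 / f_min
  n_enr <- tapply(enr, da$taxon, sum)[taxa]
  n_dep <- tapply(dep, da$taxon, sum)[taxa]
  n_da_enr <- tapply(da$da & da$direction == "enriched", da$taxon, sum)[taxa]
  n_da_dep <- tapply(da$da & da$direction == "depleted", da$taxon, sum)[taxa]
  status <- rep("none", length(taxa))
  status[n_enr >= k_core] <- "core_enriched"
  status[n_dep >= k_core] <- "core_depleted"
  status[n_enr >= k_core & n_dep >= k_core] <- "ambiguous"
  out <- data.frame(
    taxon = taxa,
    n_ecotypes_enriched = as.integer(n_enr),
    n_ecotypes_depleted = as.integer(n_dep),
    status = status,
    cluster = ifelse(n_da_enr >= n_da_dep, "cluster1_enriched",
                     "cluster2_depleted"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fold_matrix") <- fold_m
  structure(out, class = c("core_call", "data.frame"))
}

#' Tolerant-vs-sensitive fold contrast of core taxa
#'
#' For each core taxon, compares the mean drought/control fold over
#' tolerant-class ecotypes with the mean over sensitive-class ecotypes and
#' labels the taxon `higher_in_tolerant`, `lower_in_tolerant` or `equal`.
#' Rows are ranked by the tolerant/sensitive mean-fold ratio, the order
#' used to prioritise strains for validation.
#'
#' @param core a `core_call` from [call_core_responsive()] (its
#'   `fold_matrix` attribute supplies the per-ecotype folds).
#' @param design a [study_design()] giving each ecotype's tolerance class.
#' @param core_only restrict to taxa with core status (default TRUE).
#' @return data.frame: taxon, status, mean_fold_tolerant,
#'   mean_fold_sensitive, group_contrast, priority_rank.
#' @export
group_fold_contrast <- function(core, design, core_only = TRUE) {
  fold_m <- attr(core, "fold_matrix")
  if (is.null(fold_m)) stop("core call lacks a fold matrix")
  des <- unique(as.data.frame(design)[, c("ecotype", "tolerance_class")])
  cls <- stats::setNames(des$tolerance_class, des$ecotype)[colnames(fold_m)]
  if (!all(c("tolerant", "sensitive") %in% cls))
    stop("both tolerance classes must be present")
  rows <- as.data.frame(core)
  if (core_only) rows <- rows[rows$status != "none", , drop = FALSE]
  if (nrow(rows) == 0) return(rows)
  mt <- rowMeans(fold_m[rows$taxon, cls == "tolerant", drop = FALSE],
                 na.rm = TRUE)
  ms <- rowMeans(fold_m[rows$taxon, cls == "sensitive", drop = FALSE],
                 na.rm = TRUE)
  out <- data.frame(
    taxon = rows$taxon, status = rows$status,
    mean_fold_tolerant = as.numeric(mt), mean_fold_sensitive = as.numeric(ms),
    group_contrast = ifelse(mt > ms, "higher_in_tolerant",
                            ifelse(mt < ms, "lower_in_tolerant", "equal")),
    row.names = NULL, stringsAsFactors = FALSE)
  out$priority_rank <- rank(-out$mean_fold_tolerant / out$mean_fold_sensitive,
                            ties.method = "first")
  out[order(out$priority_rank), ]
}
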