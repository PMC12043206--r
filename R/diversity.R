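#' Per-sample alpha diversity
#'
#' Shannon index H = -sum p_i log p_i (natural log, zero proportions
#' skipped) and observed richness (taxa with nonzero counts).
#'
#' @param t a [count_table()].
#' @return data.frame: sample_id, shannon, richness.
#' @export
alpha_diversity <- function(t) {
  ra <- to_relative_abundance(t)
  H <- apply(ra, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  data.frame(sample_id = rownames(ra), shannon = as.numeric(H),
             richness = as.integer(rowSums(unclass(t) > 0)),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' For row-normalised relative abundances, d(a, b) = 1 - sum_i min(a_i, b_i),
#' which equals sum|a_i - b_i| / sum(a_i + b_i). Values in [0, 1], symmetric,
#' zero diagonal; a semimetric (triangle inequality not guaranteed).
#'
#' @param t a `relative_abundance` matrix from [to_relative_abundance()],
#'   or a [count_table()] (normalised first).
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
bray_curtis <- function(t) {
  if (is_count_table(t)) t <- to_relative_abundance(t)
  m <- unclass(t)
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("rows must be normalised relative abundances")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    shared <- colSums(pmin(t(m[(i + 1):n, , drop = FALSE]), m[i, ]))
    d[i, (i + 1):n] <- d[(i + 1):n, i] <- 1 - shared
  }
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centres -D^2/2 (Gower centring) and eigendecomposes. Axes are
#' ordered by eigenvalue; negative eigenvalues are reported as-is (no
#' Cailliez/Lingoes correction). Axis signs are canonicalised so the
#' largest-magnitude coordinate on each axis is positive.
#'
#' @param d symmetric distance matrix.
#' @param k number of axes to return (default: all with positive
#'   eigenvalues).
#' @return list: `coordinates` (n x k matrix), `eigenvalues` (all n),
#'   `explained` (fraction of positive inertia per returned axis).
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("pcoa needs at least 3 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  pos <- which(e$values > 1e-9 * max(abs(e$values)))
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  axes <- pos[seq_len(k)]
  coords <- e$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(e$values[axes]), nrow = k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(d), paste0("PCo", seq_len(k)))
  list(coordinates = coords, eigenvalues = e$values,
       explained = e$values[axes] / sum(e$values[pos]))
}

# sum of squared distances within each group, divided by group size;
# the workhorse shared by the observed statistic and the permutations
.ss_within <- function(d2, groups) {
  tot <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    tot <- tot + sum(d2[i, i]) / (2 * length(i))
  }
  tot
}

#' Distance-based PERMANOVA (one factor)
#'
#' Non-parametric multivariate ANOVA on a distance matrix: with n samples
#' and g groups, SS_total = sum_{i<j} d_ij^2 / n, SS_within is the pooled
#' within-group analogue, SS_between = SS_total - SS_within, pseudo-F =
#' (SS_between / (g - 1)) / (SS_within / (n - g)), R^2 =
#' SS_between / SS_total. The p-value is (1 + #{F_perm >= F_obs}) /
#' (1 + n_perm) under free (unrestricted) permutation of labels, so it can
#' never be exactly 0.
#'
#' @param d symmetric distance matrix with sample dimnames.
#' @param groups factor/character vector of group labels, aligned with the
#'   rows of `d` (or named by sample id).
#' @param n_perm number of permutations (999 is the conventional default).
#' @param seed integer seed for the permutation stream.
#' @return list of class `permanova_result`: factor sizes, `pseudo_F`, `R2`,
#'   `p`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 0L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!is.null(names(groups)) && !is.null(rownames(d)))
    groups <- groups[rownames(d)]
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must align with the distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  g <- length(sizes)
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  ss_within <- .ss_within(d2, groups)
  ss_between <- ss_total - ss_within
  f_obs <- (ss_between / (g - 1)) / (ss_within / (n - g))
  set.seed(derive_seed(seed, "permanova"))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    gp <- groups[sample.int(n)]
    ssw <- .ss_within(d2, gp)
    f_p <- ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
    if (f_p >= f_obs) exceed <- exceed + 1L
  }
  structure(list(groups = sizes, pseudo_F = f_obs,
                 R2 = ss_between / ss_total,
                 p = (1 + exceed) / (1 + n_perm), n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d perms)\n",
              x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' Pairwise PERMANOVA with BH adjustment
#'
#' Runs [permanova()] on every pair of groups and adjusts p-values with
#' Benjamini-Hochberg across the pairs.
#'
#' @inheritParams permanova
#' @return data.frame: group_a, group_b, pseudo_F, R2, p, p_adjusted.
#' @export
permanova_pairwise <- function(d, groups, n_perm = 999, seed = 0L) {
  d <- as.matrix(d)
  if (!is.null(names(groups)) && !is.null(rownames(d)))
    groups <- groups[rownames(d)]
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  pairs <- utils::combn(gs, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    keep <- groups %in% pairs[, k]
    r <- permanova(d[keep, keep, drop = FALSE], groups[keep],
                   n_perm = n_perm, seed = derive_seed(seed, paste0("pw", k)))
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               pseudo_F = r$pseudo_F, R2 = r$R2, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p)
  out
}

#' Sequential (terms-in-order) two-factor PERMANOVA
#'
#' McArdle-Anderson partitioning via hat matrices on the Gower-centred
#' matrix: R^2 of the first factor is tr(H1 G)/tr(G); the second factor's
#' R^2 is the increment tr(H12 G)/tr(G) - tr(H1 G)/tr(G), i.e. terms are
#' added sequentially as in the classical adonis default.
#'
#' @param d symmetric distance matrix.
#' @param f1,f2 group label vectors for the first and second factor.
#' @param n_perm permutations (raw labels permuted freely for each test).
#' @param seed integer seed.
#' @return data.frame with one row per factor: df, R2, pseudo_F, p.
#' @export
permanova_sequential <- function(d, f1, f2, n_perm = 999, seed = 0L) {
  d <- as.matrix(d)
  n <- nrow(d)
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  hat <- function(X) X %*% solve(crossprod(X), t(X))
  # tr(HG) = sum(H * G) for symmetric G
  trHG <- function(f1v, f2v = NULL) {
    X1 <- stats::model.matrix(~ factor(f1v))
    h1 <- sum(hat(X1) * G)
    if (is.null(f2v)) return(h1)
    X12 <- stats::model.matrix(~ factor(f1v) + factor(f2v))
    c(h1, sum(hat(X12) * G))
  }
  ss_tot <- sum(diag(G))
  df1 <- length(unique(f1)) - 1L
  df2 <- length(unique(f2)) - 1L
  df_res <- n - 1L - df1 - df2
  h <- trHG(f1, f2)
  ss1 <- h[1]; ss12 <- h[2]; ss2 <- ss12 - ss1
  ss_res <- ss_tot - ss12
  f_stat <- c((ss1 / df1) / (ss_res / df_res),
              (ss2 / df2) / (ss_res / df_res))
  set.seed(derive_seed(seed, "permanova2"))
  exceed <- c(0L, 0L)
  for (b in seq_len(n_perm)) {
    i <- sample.int(n)
    hp <- trHG(f1[i], f2[i])
    ssp1 <- hp[1]; ssp2 <- hp[2] - hp[1]; ssp_res <- ss_tot - hp[2]
    if ((ssp1 / df1) / (ssp_res / df_res) >= f_stat[1])
      exceed[1] <- exceed[1] + 1L
    if ((ssp2 / df2) / (ssp_res / df_res) >= f_stat[2])
      exceed[2] <- exceed[2] + 1L
  }
  data.frame(factor = c("factor1", "factor2"), df = c(df1, df2),
             R2 = c(ss1, ss2) / ss_tot, pseudo_F = f_stat,
             p = (1 + exceed) / (1 + n_perm), stringsAsFactors = FALSE)
}

#' Mean cumulative relative abundance of a taxon set
#'
#' Summarises how much of the community a set of (e.g. biomarker) taxa
#' accounts for: per sample the set's relative abundances are summed, then
#' averaged over the chosen samples.
#'
#' @param t a `relative_abundance` matrix (or [count_table()]).
#' @param taxa character vector of taxon ids (must exist in the table).
#' @param samples sample ids (default: all).
#' @return a single fraction in [0, 1].
#' @export
cumulative_abundance <- function(t, taxa, samples = NULL) {
  if (is_count_table(t)) t <- to_relative_abundance(t)
  m <- unclass(t)
  if (is.null(samples)) samples <- rownames(m)
  if (length(taxa) == 0) {
    warning("empty taxon set; cumulative abundance is 0")
    return(0)
  }
  missing_tax <- setdiff(taxa, colnames(m))
  if (length(missing_tax) > 0)
    stop("taxa not in table: ", paste(missing_tax, collapse = ", "))
  mean(rowSums(m[samples, taxa, drop = FALSE]))
}
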