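# Independent oracles and small fixture builders shared across tests.

# Brute-force two-sided rank-sum p-value: enumerate every C(n1+n2, n1)
# assignment of the observed pooled values to group 1 and compare rank sums.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  w <- apply(combos, 2L, function(i) sum(r[i]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w - mu) >= abs(sum(r[seq_len(n1)]) - mu) - 1e-9)
}

# Textbook step-up BH: q_(i) = min_{j >= i} ( n * p_(j) / j ), capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[o[i]] <- min(1, min(n * p[o[i:n]] / (i:n)))
  }
  q
}

# Build a cooccurrence_network by hand from an edge list.
make_net <- function(nodes, edges_ij, signs = NULL) {
  if (is.null(signs)) signs <- rep(1L, length(edges_ij))
  if (length(edges_ij) > 0) {
    e <- do.call(rbind, lapply(edges_ij, function(p) sort(p)))
    edges <- data.frame(i = e[, 1], j = e[, 2], rho = as.numeric(signs),
                        p = 0, q = 0, sign = as.integer(signs),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$i, edges$j), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = character(0), j = character(0),
                        rho = numeric(0), p = numeric(0), q = numeric(0),
                        sign = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = sort(nodes), edges = edges,
                 context = list(ecotype = NA, treatment = NA),
                 n_samples = NA_integer_),
            class = "cooccurrence_network")
}

# Wrap a plain matrix as a relative_abundance table (rows renormalised).
make_relab <- function(m) {
  m <- m / rowSums(m)
  structure(m, class = c("relative_abundance", "matrix", "array"))
}

# Independently shuffle each taxon across samples (breaks associations,
# keeps marginals), then renormalise rows.
shuffle_taxa <- function(ra, seed) {
  set.seed(seed)
  m <- unclass(ra)
  sh <- apply(m, 2L, sample)
  rownames(sh) <- rownames(m)
  make_relab(sh)
}
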