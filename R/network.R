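# two-sided p for a Spearman coefficient via the t approximation used by
# common co-occurrence tools (t = rho * sqrt((n-2)/(1-rho^2)); |rho| = 1
# gives p = 0). An exact-permutation alternative would make edges at
# n = 4 unattainable under any FDR threshold, so the t form is the default.
.spearman_p <- function(rho, n) {
  p <- rep(1, length(rho))
  ok <- abs(rho) < 1
  tt <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), n - 2)
  p[!ok] <- 0
  p
}

#' Build a co-occurrence network for one (ecotype, treatment) context
#'
#' Candidate taxa must exceed `abund_min` mean relative abundance within the
#' context samples (default 0.2%) and occur in at least `min_prev` of them.
#' All candidate pairs get a Spearman coefficient (average ranks on ties);
#' p-values are BH-adjusted over all tested pairs of this network and an
#' edge is kept when |rho| >= `rho_min` and q < `q_max`. Edge signs are
#' retained; `positive_only = TRUE` reproduces the stricter
#' positive-association-only reading.
#'
#' @param t a `relative_abundance` matrix or [count_table()].
#' @param design a [study_design()]; `ecotype`/`treatment` select the
#'   context. Pass `design = NULL` to use all rows of `t` as one context.
#' @param ecotype,treatment context selectors.
#' @param abund_min mean relative-abundance filter.
#' @param min_prev minimum number of samples with nonzero abundance.
#' @param rho_min absolute Spearman threshold.
#' @param q_max BH-adjusted p threshold.
#' @param positive_only drop negative edges.
#' @return `cooccurrence_network`: list with `nodes`, `edges` (data.frame
#'   i, j, rho, p, q, sign with i < j canonically by node id), `context`,
#'   `n_samples`.
#' @export
build_network <- function(t, design = NULL, ecotype = NULL, treatment = NULL,
                          abund_min = 0.002, min_prev = 2, rho_min = 0.9,
                          q_max = 0.05, positive_only = FALSE) {
  if (is_count_table(t)) t <- to_relative_abundance(t)
  m <- unclass(t)
  if (!is.null(design)) {
    des <- as.data.frame(design)
    keep <- des$sample_id[(is.null(ecotype) | des$ecotype == ecotype) &
                            (is.null(treatment) | des$treatment == treatment)]
    m <- m[intersect(rownames(m), keep), , drop = FALSE]
  }
  if (nrow(m) < 4) stop("network context needs at least 4 samples")
  elig <- colMeans(m) > abund_min & colSums(m > 0) >= min_prev
  nodes <- sort(colnames(m)[elig])
  context <- list(ecotype = ecotype, treatment = treatment)
  empty <- data.frame(i = character(0), j = character(0), rho = numeric(0),
                      p = numeric(0), q = numeric(0), sign = integer(0),
                      stringsAsFactors = FALSE)
  if (length(nodes) < 2) {
    warning("fewer than 2 eligible taxa; returning an empty network")
    return(structure(list(nodes = nodes, edges = empty, context = context,
                          n_samples = nrow(m)),
                     class = "cooccurrence_network"))
  }
  sub <- m[, nodes, drop = FALSE]
  rho <- stats::cor(sub, method = "spearman")
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  rv <- rho[ut]
  pv <- .spearman_p(rv, nrow(sub))
  qv <- bh_adjust(pv)
  keep <- !is.na(rv) & abs(rv) >= rho_min & qv < q_max
  if (positive_only) keep <- keep & rv > 0
  edges <- data.frame(i = nodes[ut[keep, 1]], j = nodes[ut[keep, 2]],
                      rho = rv[keep], p = pv[keep], q = qv[keep],
                      sign = as.integer(sign(rv[keep])),
                      stringsAsFactors = FALSE)
  swap <- edges$i > edges$j
  tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, context = context,
                 n_samples = nrow(m)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (%d negative)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign < 0)))
  invisible(x)
}

# igraph object over all nodes (including isolated ones), unweighted
.as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(net$edges$i, net$nodes),
                                    match(net$edges$j, net$nodes)))
    g <- igraph::set_edge_attr(g, "sign", value = net$edges$sign)
    g <- igraph::set_edge_attr(g, "rho", value = net$edges$rho)
  }
  g
}

#' Topology metrics of a co-occurrence network
#'
#' Connectance E / (N(N-1)/2), average degree 2E/N, normalised unweighted
#' shortest-path betweenness, and the modularity Q of a deterministic
#' greedy (agglomerative, fast-greedy) partition of the unweighted graph.
#'
#' @param net a `cooccurrence_network`.
#' @return list of class `network_metrics`: `n_nodes`, `n_edges`,
#'   `connectance`, `average_degree`, `modularity`, `degree`,
#'   `betweenness`, `membership` (named vectors).
#' @export
topology <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  n <- length(net$nodes)
  e <- nrow(net$edges)
  if (n == 0) {
    return(structure(list(n_nodes = 0L, n_edges = 0L, connectance = NA_real_,
                          average_degree = NA_real_, modularity = NA_real_,
                          degree = numeric(0), betweenness = numeric(0),
                          membership = integer(0)),
                     class = "network_metrics"))
  }
  g <- .as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  if (e > 0) {
    comm <- igraph::cluster_fast_greedy(g)
    memb <- igraph::membership(comm)
    q <- igraph::modularity(g, memb)
  } else {
    memb <- stats::setNames(seq_len(n), net$nodes)
    q <- NA_real_
  }
  structure(list(
    n_nodes = n, n_edges = e,
    connectance = if (n > 1) e / (n * (n - 1) / 2) else NA_real_,
    average_degree = 2 * e / n,
    modularity = q, degree = deg, betweenness = btw,
    membership = stats::setNames(as.integer(memb), net$nodes)),
    class = "network_metrics")
}

#' Community cohesion (positive / negative / total)
#'
#' Null-corrected, abundance-weighted association statistic used as a
#' stability proxy. Pairwise Pearson correlations between taxa are
#' corrected by subtracting the mean correlation over `n_null`
#' taxon-shuffled tables (each taxon's values permuted independently across
#' samples). Per taxon, positive connectedness is the mean over all other
#' taxa of the positive part of the corrected correlation (negative
#' analogous); per-sample cohesion is the relative-abundance-weighted sum
#' of connectedness, and the reported values average over the context
#' samples. `total = positive + |negative|`.
#'
#' @param t a `relative_abundance` matrix or [count_table()].
#' @param samples sample ids of the context (default: all rows).
#' @param n_null number of shuffled null tables.
#' @param seed integer seed for the shuffles.
#' @return list: `positive` (>= 0), `negative` (<= 0), `total`,
#'   `connectedness` (data.frame per taxon).
#' @export
cohesion <- function(t, samples = NULL, n_null = 200, seed = 0L) {
  if (is_count_table(t)) t <- to_relative_abundance(t)
  m <- unclass(t)
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (nrow(m) < 4) stop("cohesion needs at least 4 samples")
  keep <- apply(m, 2L, stats::sd) > 0
  if (any(!keep))
    warning(sum(!keep), " constant taxa excluded from cohesion")
  m <- m[, keep, drop = FALSE]
  nt <- ncol(m)
  if (nt < 2) stop("cohesion needs at least 2 varying taxa")
  obs <- stats::cor(m)
  set.seed(derive_seed(seed, "cohesion"))
  null_mean <- matrix(0, nt, nt)
  for (b in seq_len(n_null)) {
    sh <- apply(m, 2L, sample)
    null_mean <- null_mean + stats::cor(sh)
  }
  null_mean <- null_mean / n_null
  corr <- obs - null_mean
  diag(corr) <- 0
  conn_pos <- rowSums(pmax(corr, 0)) / (nt - 1)
  conn_neg <- rowSums(pmin(corr, 0)) / (nt - 1)
  coh_pos <- as.numeric(m %*% conn_pos)
  coh_neg <- as.numeric(m %*% conn_neg)
  pos <- mean(coh_pos); neg <- mean(coh_neg)
  list(positive = pos, negative = neg, total = pos + abs(neg),
       connectedness = data.frame(taxon = colnames(m),
                                  positive = conn_pos, negative = conn_neg,
                                  row.names = NULL, stringsAsFactors = FALSE))
}

#' Export a network
#'
#' @param net a `cooccurrence_network`.
#' @param path output file.
#' @param format `"graphml"` or `"tsv"` (edge list).
#' @export
write_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(.as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}
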