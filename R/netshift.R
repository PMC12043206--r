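# neighbor sets of every node, as a named list of character vectors
.neighbor_sets <- function(net) {
  nb <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (v in net$nodes) nb[[v]] <- character(0)
  if (nrow(net$edges) > 0) {
    for (k in seq_len(nrow(net$edges))) {
      i <- net$edges$i[k]; j <- net$edges$j[k]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

#' Neighbor-shift (NESH) scores between paired networks
#'
#' Quantifies per-node neighborhood turnover from a control network to a
#' case (drought) network. For each node v common to both networks, with
#' neighbor sets A (control) and B (case) restricted to the common nodes,
#' NESH(v) is the case-specific-neighbor fraction |B \ A| / |B| (0 when B
#' is empty): 0 for an unchanged neighborhood, 1 when every case neighbor
#' is newly gained. Scaled NESH is the min-max rescaling over common nodes
#' (all-equal scores rescale to 0). Edges among common nodes are classified
#' `case_only` / `control_only` / `shared`.
#'
#' @param control,case `cooccurrence_network` objects.
#' @return list of class `driver_report`: `scores` (data.frame per common
#'   node: node, degree/betweenness in both networks, nesh, nesh_scaled),
#'   `edges` (classified union edge list), `common_nodes`.
#' @export
nesh_scores <- function(control, case) {
  common <- intersect(control$nodes, case$nodes)
  if (length(common) == 0) {
    warning("no common nodes between the paired networks")
    return(structure(list(scores = data.frame(), edges = data.frame(),
                          common_nodes = character(0)),
                     class = "driver_report"))
  }
  common <- sort(common)
  nb_a <- .neighbor_sets(control)
  nb_b <- .neighbor_sets(case)
  top_a <- topology(control)
  top_b <- topology(case)
  nesh <- vapply(common, function(v) {
    A <- intersect(nb_a[[v]], common)
    B <- intersect(nb_b[[v]], common)
    if (length(B) == 0) 0 else length(setdiff(B, A)) / length(B)
  }, numeric(1))
  rng <- range(nesh)
  scaled <- if (diff(rng) == 0) rep(0, length(nesh)) else
    (nesh - rng[1]) / diff(rng)
  scores <- data.frame(
    node = common,
    degree_control = as.integer(top_a$degree[common]),
    degree_case = as.integer(top_b$degree[common]),
    betweenness_control = as.numeric(top_a$betweenness[common]),
    betweenness_case = as.numeric(top_b$betweenness[common]),
    nesh = as.numeric(nesh), nesh_scaled = as.numeric(scaled),
    row.names = NULL, stringsAsFactors = FALSE)
  ekey <- function(net) {
    e <- net$edges
    e <- e[e$i %in% common & e$j %in% common, , drop = FALSE]
    paste(e$i, e$j, sep = "\r")
  }
  ka <- ekey(control); kb <- ekey(case)
  all_k <- sort(union(ka, kb))
  parts <- strsplit(all_k, "\r", fixed = TRUE)
  edges <- data.frame(
    i = vapply(parts, `[`, "", 1), j = vapply(parts, `[`, "", 2),
    class = ifelse(all_k %in% ka & all_k %in% kb, "shared",
                   ifelse(all_k %in% kb, "case_only", "control_only")),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(scores = scores, edges = edges, common_nodes = common),
            class = "driver_report")
}

#' Call driver taxa from a NESH report
#'
#' A node is a driver when its betweenness increased from control to case
#' AND its scaled NESH reaches `tau`. The cited network-comparison tool
#' publishes no threshold; the default `tau` is the mean scaled NESH over
#' common nodes, which adapts to how much turnover the pair shows overall.
#'
#' @param report a `driver_report` from [nesh_scores()].
#' @param tau scaled-NESH threshold in [0, 1], or `NULL` for the mean.
#' @return the report with `scores$is_driver` filled and `drivers` (node
#'   ids) attached.
#' @export
identify_drivers <- function(report, tau = NULL) {
  stopifnot(inherits(report, "driver_report"))
  s <- report$scores
  if (nrow(s) == 0) {
    report$drivers <- character(0)
    return(report)
  }
  if (is.null(tau)) tau <- mean(s$nesh_scaled)
  s$is_driver <- s$betweenness_case > s$betweenness_control &
    s$nesh_scaled >= tau
  report$scores <- s
  report$tau <- tau
  report$drivers <- s$node[s$is_driver]
  report
}

#' Cross-ecotype core driver genera
#'
#' Aggregates per-ecotype driver nodes to genus labels (sentinel convention
#' of [rank_labels()]) and flags genera that act as drivers in at least
#' `min_ecotypes` ecotypes as core drivers. When a bulk-soil report is
#' supplied, the root/bulk overlap of driver genera is computed.
#'
#' @param reports named list of driver reports (after
#'   [identify_drivers()]), one per ecotype.
#' @param taxonomy a [taxonomy_table()] mapping node taxa to genera.
#' @param min_ecotypes minimum number of ecotypes for core status.
#' @param bulk_report optional driver report of the bulk-soil pseudo-
#'   ecotype.
#' @return list: `table` (data.frame genus, n_ecotypes, ecotypes, core,
#'   ranked by support), `core_genera`, `bulk_overlap` (NULL without a bulk
#'   report).
#' @export
core_drivers <- function(reports, taxonomy, min_ecotypes = 4,
                         bulk_report = NULL) {
  if (length(reports) < min_ecotypes)
    stop("need reports from at least min_ecotypes = ", min_ecotypes,
         " ecotypes")
  if (is.null(names(reports)) || any(names(reports) == ""))
    stop("reports must be named by ecotype")
  lab <- rank_labels(taxonomy, "genus")
  per_eco <- lapply(reports, function(r) {
    drv <- r$drivers
    missing_tax <- setdiff(drv, names(lab))
    if (length(missing_tax) > 0)
      stop("driver taxa missing from taxonomy: ",
           paste(missing_tax, collapse = ", "))
    unique(lab[drv])
  })
  genera <- sort(unique(unlist(per_eco)))
  if (length(genera) == 0) {
    return(list(table = data.frame(genus = character(0),
                                   n_ecotypes = integer(0),
                                   ecotypes = character(0),
                                   core = logical(0)),
                core_genera = character(0), bulk_overlap = NULL))
  }
  hits <- vapply(genera, function(g)
    sum(vapply(per_eco, function(v) g %in% v, logical(1))), integer(1))
  ecos <- vapply(genera, function(g)
    paste(names(per_eco)[vapply(per_eco, function(v) g %in% v, logical(1))],
          collapse = ","), character(1))
  tab <- data.frame(genus = genera, n_ecotypes = as.integer(hits),
                    ecotypes = ecos, core = hits >= min_ecotypes,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$n_ecotypes, tab$genus), ]
  rownames(tab) <- NULL
  bulk_overlap <- NULL
  if (!is.null(bulk_report)) {
    bulk_gen <- unique(lab[bulk_report$drivers])
    root_gen <- unique(unlist(per_eco))
    bulk_overlap <- list(root_only = sort(setdiff(root_gen, bulk_gen)),
                         bulk_only = sort(setdiff(bulk_gen, root_gen)),
                         shared = sort(intersect(root_gen, bulk_gen)))
  }
  list(table = tab, core_genera = tab$genus[tab$core],
       bulk_overlap = bulk_overlap)
}

#' Export a combined control/case graph with edge classification
#'
#' Writes the union graph over common nodes as GraphML with an edge
#' attribute `class` in {case_only, control_only, shared} and node
#' attributes `nesh_scaled` and `is_driver`.
#'
#' @param report a `driver_report` after [identify_drivers()].
#' @param path output GraphML path.
#' @export
write_driver_graph <- function(report, path) {
  s <- report$scores
  g <- igraph::make_empty_graph(n = nrow(s), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = s$node)
  g <- igraph::set_vertex_attr(g, "nesh_scaled", value = s$nesh_scaled)
  g <- igraph::set_vertex_attr(g, "is_driver",
                               value = as.integer(isTRUE(s$is_driver) |
                                                    s$node %in% report$drivers))
  if (nrow(report$edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(report$edges$i, s$node),
                                    match(report$edges$j, s$node)))
    g <- igraph::set_edge_attr(g, "class", value = report$edges$class)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
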