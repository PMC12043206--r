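#' Default pipeline configuration
#'
#' Thresholds mirror the screening procedure: per-ecotype DA at mean
#' relative abundance > 0.1% and Wilcoxon p < 0.05 (unadjusted); core
#' status at fold >= 1.2 in >= 5 ecotypes; networks over taxa at > 0.2%
#' abundance in >= 2 samples with |Spearman rho| >= 0.9 and BH q < 0.05;
#' core drivers in >= 4 ecotypes; 97% identity for OTU clustering and
#' ASV-isolate matching. One integer seed feeds every stochastic stage
#' through per-stage substreams.
#'
#' @param ... overrides of the default entries.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 0L,
    synthetic = TRUE,
    n_perm = 999,
    abundance_min = 0.001, alpha = 0.05, da_adjust = "none",
    k_core = 5, f_min = 1.2, eps = 1e-6,
    net_abund_min = 0.002, net_min_prev = 2,
    rho_min = 0.9, q_max = 0.05,
    cohesion_n_null = 200,
    driver_min_ecotypes = 4,
    id_min = 0.97,
    n_isolates = 40, divergence = 0.01,
    counts = NULL, counts_format = "tsv", design = NULL, taxonomy = NULL,
    asv_fasta = NULL, isolate_fasta = NULL, phenotypes = NULL,
    out_dir = "coreresponder_out")
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full inference chain
#'
#' Executes diversity -> per-ecotype differential abundance -> core-ASV
#' calling -> co-occurrence networks -> driver (NESH) detection -> isolate
#' matching -> phenotype ranking, writing all result tables plus a
#' machine-readable JSON run log (thresholds, seed, stage inventory) to
#' `config$out_dir`. With `synthetic = TRUE` (default) inputs come from
#' [generate_community()] under the configured seed; otherwise file paths
#' in the config are read. Identical config + seed reproduces identical
#' outputs byte for byte.
#'
#' @param config a list from [default_config()], or a path to a JSON file
#'   of overrides.
#' @return invisibly, a list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config))
    config <- do.call(default_config,
                      jsonlite::read_json(config, simplifyVector = TRUE))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  seqs <- NULL
  pheno <- NULL
  if (isTRUE(cfg$synthetic)) {
    gen <- .stage("synthetic_data", {
      spec <- synthetic_spec(seed = cfg$seed)
      g <- generate_community(spec)
      g$sequences <- generate_sequences(g$truth, n_isolates = cfg$n_isolates,
                                        divergence = cfg$divergence,
                                        seed = cfg$seed)
      g$phenotypes <- generate_phenotypes(g$truth, seed = cfg$seed)
      g
    })
    counts <- gen$counts; design <- gen$design; taxonomy <- gen$taxonomy
    seqs <- gen$sequences; pheno <- gen$phenotypes
    .stage("synthetic_data", {
      write_count_table(counts, out("counts.tsv"))
      jsonlite::write_json(gen$truth[c("taxa", "ecotypes")],
                           out("planted_truth.json"), digits = NA,
                           dataframe = "columns")
    })
  } else {
    counts <- .stage("io", read_count_table(cfg$counts, cfg$counts_format))
    design <- .stage("io", read_study_design(cfg$design))
    taxonomy <- .stage("io", read_taxonomy(cfg$taxonomy))
    if (!is.null(cfg$asv_fasta) && !is.null(cfg$isolate_fasta))
      seqs <- .stage("io", list(asv = read_fasta(cfg$asv_fasta),
                                isolates = read_fasta(cfg$isolate_fasta)))
    if (!is.null(cfg$phenotypes))
      pheno <- .stage("io", read_phenotypes(cfg$phenotypes))
  }

  counts <- .stage("filter", filter_singletons(counts))
  check_design(design, counts)
  relab <- to_relative_abundance(counts)
  des <- as.data.frame(design)
  root_ecos <- sort(unique(des$ecotype[des$tolerance_class != "bulk"]))
  bulk_ecos <- sort(unique(des$ecotype[des$tolerance_class == "bulk"]))

  div <- .stage("diversity", {
    alpha <- alpha_diversity(counts)
    d <- bray_curtis(relab)
    ord <- pcoa(d)
    grp_eco <- stats::setNames(des$ecotype, des$sample_id)
    grp_trt <- stats::setNames(des$treatment, des$sample_id)
    pmv <- permanova_sequential(d, grp_eco[rownames(d)], grp_trt[rownames(d)],
                                n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, "adonis"))
    pmv$factor <- c("ecotype", "treatment")
    .write_tsv(alpha, out("alpha_diversity.tsv"))
    utils::write.table(round(d, 10), out("bray_curtis.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    .write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                          ord$coordinates[, 1:2, drop = FALSE]),
               out("pcoa.tsv"))
    jsonlite::write_json(list(eigenvalues = ord$eigenvalues,
                              explained = ord$explained),
                         out("pcoa_eigen.json"), digits = NA)
    .write_tsv(pmv, out("permanova.tsv"))
    list(alpha = alpha, dist = d, pcoa = ord, permanova = pmv)
  })

  da_list <- .stage("differential", {
    lst <- lapply(root_ecos, function(e)
      per_ecotype_da(relab, design, e, abundance_min = cfg$abundance_min,
                     alpha = cfg$alpha, adjust = cfg$da_adjust,
                     eps = cfg$eps))
    names(lst) <- root_ecos
    .write_tsv(do.call(rbind, lapply(lst, as.data.frame)), out("da.tsv"))
    lst
  })

  core <- .stage("core_call", {
    cc <- call_core_responsive(da_list, k_core = cfg$k_core,
                               f_min = cfg$f_min)
    fm <- attr(cc, "fold_matrix")
    .write_tsv(as.data.frame(cc), out("core_calls.tsv"))
    utils::write.table(round(fm, 10), out("fold_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    cc
  })

  contrast <- .stage("group_contrast", {
    gc <- if (any(as.data.frame(core)$status != "none"))
      group_fold_contrast(core, design) else
        data.frame()
    if (nrow(gc) > 0) .write_tsv(gc, out("group_contrast.tsv"))
    gc
  })

  nets <- .stage("networks", {
    res <- list()
    metrics <- list()
    for (e in c(root_ecos, bulk_ecos)) {
      for (tr in c("control", "drought")) {
        net <- suppressWarnings(
          build_network(relab, design, e, tr,
                        abund_min = cfg$net_abund_min,
                        min_prev = cfg$net_min_prev,
                        rho_min = cfg$rho_min, q_max = cfg$q_max))
        top <- topology(net)
        coh <- tryCatch(
          cohesion(relab,
                   des$sample_id[des$ecotype == e & des$treatment == tr],
                   n_null = cfg$cohesion_n_null,
                   seed = derive_seed(cfg$seed, paste0("coh-", e, "-", tr))),
          error = function(err) list(positive = NA_real_,
                                     negative = NA_real_, total = NA_real_))
        key <- paste(e, tr, sep = "_")
        res[[key]] <- net
        metrics[[key]] <- data.frame(
          ecotype = e, treatment = tr, n_nodes = top$n_nodes,
          n_edges = top$n_edges, connectance = top$connectance,
          average_degree = top$average_degree, modularity = top$modularity,
          cohesion_positive = coh$positive, cohesion_negative = coh$negative,
          cohesion_total = coh$total, stringsAsFactors = FALSE)
        write_network(net, out(paste0("network_", key, ".tsv")), "tsv")
      }
    }
    .write_tsv(do.call(rbind, metrics), out("network_metrics.tsv"))
    res
  })

  drivers <- .stage("netshift", {
    reports <- list()
    for (e in root_ecos) {
      rep_e <- nesh_scores(nets[[paste0(e, "_control")]],
                           nets[[paste0(e, "_drought")]])
      reports[[e]] <- identify_drivers(rep_e)
      if (nrow(reports[[e]]$scores) > 0)
        .write_tsv(reports[[e]]$scores, out(paste0("nesh_", e, ".tsv")))
    }
    bulk_rep <- NULL
    if (length(bulk_ecos) > 0) {
      b <- bulk_ecos[1]
      bulk_rep <- identify_drivers(
        nesh_scores(nets[[paste0(b, "_control")]],
                    nets[[paste0(b, "_drought")]]))
    }
    cd <- core_drivers(reports, taxonomy,
                       min_ecotypes = cfg$driver_min_ecotypes,
                       bulk_report = bulk_rep)
    .write_tsv(cd$table, out("core_drivers.tsv"))
    list(reports = reports, core = cd)
  })

  match <- NULL
  if (!is.null(seqs)) {
    match <- .stage("strain_match", {
      cl <- dereplicate_and_cluster(seqs$isolates, id_min = cfg$id_min)
      core_taxa <- as.data.frame(core)
      core_taxa <- core_taxa$taxon[core_taxa$status == "core_enriched"]
      query <- if (length(core_taxa) > 0 &&
                   all(core_taxa %in% names(seqs$asv)))
        seqs$asv[core_taxa] else seqs$asv[seq_len(min(20, length(seqs$asv)))]
      mr <- match_asvs(query, cl, id_min = cfg$id_min)
      .write_tsv(cl$clusters, out("otu_clusters.tsv"))
      .write_tsv(as.data.frame(mr), out("asv_matches.tsv"))
      list(clustering = cl, matches = mr)
    })
  }

  pheno_res <- NULL
  if (!is.null(pheno)) {
    pheno_res <- .stage("phenotype", {
      tol <- rank_tolerance(pheno)
      prot <- rank_protection(pheno)
      .write_tsv(data.frame(ecotype = names(tol$index),
                            tolerance_index = as.numeric(tol$index),
                            protection_effect =
                              as.numeric(prot$effect[names(tol$index)])),
                 out("phenotype_ranking.tsv"))
      list(tolerance = tol, protection = prot)
    })
  }

  log <- list(
    package = "coreresponder",
    seed = cfg$seed,
    thresholds = cfg[c("abundance_min", "alpha", "da_adjust", "k_core",
                       "f_min", "eps", "net_abund_min", "net_min_prev",
                       "rho_min", "q_max", "cohesion_n_null",
                       "driver_min_ecotypes", "id_min", "n_perm")],
    n_samples = nrow(counts), n_taxa = ncol(counts),
    ecotypes = root_ecos, bulk = bulk_ecos,
    stages = c("diversity", "differential", "core_call", "group_contrast",
               "networks", "netshift",
               if (!is.null(match)) "strain_match",
               if (!is.null(pheno_res)) "phenotype"))
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(counts = counts, design = design, taxonomy = taxonomy,
                 diversity = div, da = da_list, core = core,
                 contrast = contrast, networks = nets, drivers = drivers,
                 match = match, phenotypes = pheno_res,
                 out_dir = cfg$out_dir))
}
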