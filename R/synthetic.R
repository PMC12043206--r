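#' Specification of a synthetic drought-response community
#'
#' Describes the world the generator draws from: a multi-ecotype,
#' two-treatment, replicated 16S survey with planted drought effects,
#' tolerance-class fold differences and correlated taxon modules. Counts are
#' Dirichlet-multinomial draws around a log-normal base composition;
#' module correlation enters through one latent Gaussian factor per module
#' scaling member abundances before renormalisation (Gaussian-copula style).
#'
#' Taxon ids `ASV0001..` are assigned in decreasing base-abundance order, so
#' effect/module taxon sets are given as abundance ranks (1 = most abundant).
#'
#' @param n_ecotypes number of ecotypes; the first half is labelled
#'   `tolerant`, the second `sensitive`.
#' @param n_reps biological replicates per (ecotype, treatment).
#' @param n_taxa community richness.
#' @param depth_range integer range of per-sample read depth (uniform draw).
#' @param base_meanlog,base_sdlog log-normal parameters of the base
#'   mean-abundance profile before renormalisation.
#' @param dm_precision Dirichlet concentration; replicate-level noise of a
#'   taxon at proportion p has CV ~ 1/sqrt(p * dm_precision).
#' @param planted_effects data.frame with columns `rank` (taxon abundance
#'   rank), `fold` (> 0; > 1 enriched, < 1 depleted under drought) and
#'   `n_ecotypes_affected` (effects are planted in ecotypes drawn evenly
#'   from both tolerance classes).
#' @param group_differential extra fold multiplier applied to planted taxa
#'   in drought samples of tolerant-class ecotypes.
#' @param network_modules data.frame with columns `rank_from`, `rank_to`
#'   (inclusive taxon-rank span) and `lambda` (loading in [0, 1]).
#' @param module_sigma scale (log-abundance SD) of the shared latent factor.
#' @param seed integer master seed; every stage derives its own substream.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_ecotypes = 10, n_reps = 4, n_taxa = 300,
                           depth_range = c(5000L, 20000L),
                           base_meanlog = 0, base_sdlog = 1.5,
                           dm_precision = 5000,
                           planted_effects = data.frame(
                             rank = 11:20, fold = 3,
                             n_ecotypes_affected = 6),
                           group_differential = 1.5,
                           network_modules = data.frame(
                             rank_from = c(21L, 31L), rank_to = c(28L, 38L),
                             lambda = 0.9),
                           module_sigma = 0.6,
                           seed = 0L) {
  spec <- list(n_ecotypes = as.integer(n_ecotypes),
               n_reps = as.integer(n_reps), n_taxa = as.integer(n_taxa),
               depth_range = as.integer(depth_range),
               base_meanlog = base_meanlog, base_sdlog = base_sdlog,
               dm_precision = dm_precision,
               planted_effects = planted_effects,
               group_differential = group_differential,
               network_modules = network_modules,
               module_sigma = module_sigma, seed = as.integer(seed))
  if (!is.null(spec$planted_effects) && nrow(spec$planted_effects) > 0) {
    pe <- spec$planted_effects
    if (any(pe$fold <= 0)) stop("planted folds must be > 0")
    if (any(pe$rank < 1 | pe$rank > n_taxa))
      stop("planted taxon rank out of range 1..", n_taxa)
    if (anyDuplicated(pe$rank)) stop("planted taxon sets must be disjoint")
  }
  if (!is.null(spec$network_modules) && nrow(spec$network_modules) > 0) {
    nm <- spec$network_modules
    if (any(nm$lambda < 0 | nm$lambda > 1)) stop("lambda must lie in [0,1]")
    if (any(nm$rank_from < 1 | nm$rank_to > n_taxa | nm$rank_from > nm$rank_to))
      stop("module taxon rank span out of range 1..", n_taxa)
    spans <- unlist(Map(seq, nm$rank_from, nm$rank_to))
    if (anyDuplicated(spans)) stop("module taxon sets must be disjoint")
  }
  structure(spec, class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
null_synthetic_spec <- function(...) {
  synthetic_spec(planted_effects = NULL, network_modules = NULL, ...)
}

# Deterministic per-stage substream: mixes the master seed with the stage
# name so stages can be re-run independently. Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Generate a synthetic community with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts` ([count_table()]), `design`
#'   ([study_design()]), `taxonomy` ([taxonomy_table()]) and `truth` (the
#'   planted ground truth: `$taxa` per-taxon status/fold/module/affected
#'   ecotypes, `$ecotypes` tolerance classes and phenotype effects).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, "community"))

  n_tol <- ceiling(spec$n_ecotypes / 2)
  ecotypes <- sprintf("Eco%02d", seq_len(spec$n_ecotypes))
  classes <- rep(c("tolerant", "sensitive"),
                 c(n_tol, spec$n_ecotypes - n_tol))

  base <- sort(stats::rlnorm(spec$n_taxa, spec$base_meanlog, spec$base_sdlog),
               decreasing = TRUE)
  base <- base / sum(base)
  taxa <- sprintf("ASV%04d", seq_len(spec$n_taxa))

  # per-taxon truth bookkeeping
  truth_taxa <- data.frame(taxon_id = taxa, base_abundance = base,
                           status = "null", fold = 1,
                           affected_ecotypes = "", module = NA_integer_,
                           stringsAsFactors = FALSE)
  affected_by_taxon <- vector("list", spec$n_taxa)
  pe <- spec$planted_effects
  if (!is.null(pe) && nrow(pe) > 0) {
    for (k in seq_len(nrow(pe))) {
      i <- pe$rank[k]
      n_aff <- pe$n_ecotypes_affected[k]
      # draw affected ecotypes evenly from both classes
      n_aff_tol <- ceiling(n_aff / 2)
      aff <- c(ecotypes[classes == "tolerant"][seq_len(
                 min(n_aff_tol, n_tol))],
               ecotypes[classes == "sensitive"][seq_len(
                 min(n_aff - n_aff_tol, spec$n_ecotypes - n_tol))])
      affected_by_taxon[[i]] <- aff
      truth_taxa$status[i] <- if (pe$fold[k] > 1) "enriched" else
        if (pe$fold[k] < 1) "depleted" else "null"
      truth_taxa$fold[i] <- pe$fold[k]
      truth_taxa$affected_ecotypes[i] <- paste(aff, collapse = ",")
    }
  }
  nm <- spec$network_modules
  module_members <- list()
  if (!is.null(nm) && nrow(nm) > 0) {
    for (k in seq_len(nrow(nm))) {
      idx <- seq(nm$rank_from[k], nm$rank_to[k])
      module_members[[k]] <- idx
      truth_taxa$module[idx] <- k
    }
  }

  design <- expand.grid(replicate = seq_len(spec$n_reps),
                        treatment = c("control", "drought"),
                        ecotype = ecotypes, stringsAsFactors = FALSE)
  design <- design[, c("ecotype", "treatment", "replicate")]
  design$tolerance_class <- classes[match(design$ecotype, ecotypes)]
  design$sample_id <- sprintf("%s_%s_r%d", design$ecotype,
                              substr(design$treatment, 1, 1),
                              design$replicate)
  n_samples <- nrow(design)

  counts <- matrix(0L, nrow = n_samples, ncol = spec$n_taxa,
                   dimnames = list(design$sample_id, taxa))
  depths <- if (spec$depth_range[1] == spec$depth_range[2])
    rep(spec$depth_range[1], n_samples) else
    sample(spec$depth_range[1]:spec$depth_range[2], n_samples, replace = TRUE)

  for (s in seq_len(n_samples)) {
    p <- base
    if (design$treatment[s] == "drought" && !is.null(pe) && nrow(pe) > 0) {
      for (k in seq_len(nrow(pe))) {
        i <- pe$rank[k]
        if (design$ecotype[s] %in% affected_by_taxon[[i]]) {
          f <- pe$fold[k]
          if (design$tolerance_class[s] == "tolerant")
            f <- f * spec$group_differential
          p[i] <- p[i] * f
        }
      }
    }
    if (length(module_members) > 0) {
      for (k in seq_along(module_members)) {
        z <- stats::rnorm(1)
        idx <- module_members[[k]]
        p[idx] <- p[idx] * exp(nm$lambda[k] * spec$module_sigma * z)
      }
    }
    p <- p / sum(p)
    gam <- stats::rgamma(spec$n_taxa, shape = p * spec$dm_precision)
    if (sum(gam) == 0) gam <- p
    counts[s, ] <- stats::rmultinom(1, size = depths[s], prob = gam / sum(gam))
  }

  # deterministic synthetic taxonomy: ~55 genera nested in 18 families,
  # 6 orders, 3 phyla; ~10% of taxa left genus-unannotated to exercise the
  # sentinel-label convention
  g_of <- ((seq_len(spec$n_taxa) - 1L) %% 55L) + 1L
  f_of <- ((g_of - 1L) %/% 3L) + 1L
  o_of <- ((f_of - 1L) %/% 3L) + 1L
  p_of <- ((o_of - 1L) %% 3L) + 1L
  genus <- sprintf("Genus%02d", g_of)
  genus[seq_len(spec$n_taxa) %% 10L == 0L] <- NA_character_
  taxonomy <- taxonomy_table(data.frame(
    taxon_id = taxa, kingdom = "Bacteria",
    phylum = sprintf("Phylum%02d", p_of),
    class = sprintf("Class%02d", o_of),
    order = sprintf("Order%02d", o_of),
    family = sprintf("Family%02d", f_of),
    genus = genus, species = NA_character_,
    stringsAsFactors = FALSE))

  truth_eco <- data.frame(
    ecotype = ecotypes, tolerance_class = classes,
    rfw_sterilized = ifelse(classes == "tolerant", 0.45, 0.35),
    protection = ifelse(classes == "tolerant", 1.6, 1.05),
    stringsAsFactors = FALSE)
  truth_eco$rfw_live <- truth_eco$rfw_sterilized * truth_eco$protection

  list(counts = count_table(counts),
       design = study_design(design[, c("sample_id", "ecotype", "treatment",
                                        "tolerance_class", "replicate")]),
       taxonomy = taxonomy,
       truth = structure(list(taxa = truth_taxa, ecotypes = truth_eco,
                              spec = spec),
                         class = "planted_truth"))
}

#' Generate V3-V4-like ASV and isolate sequences with known pairing
#'
#' Random ~420 nt ACGT sequences stand in for denoised amplicons; each
#' isolate is copied from a chosen source ASV with i.i.d. substitutions
#' (always to a different base, no indels), so expected identity is exactly
#' 1 - divergence and stays analytic for tests.
#'
#' @param truth a `planted_truth` from [generate_community()] (its taxon ids
#'   name the ASVs); alternatively an integer number of ASVs.
#' @param n_isolates isolates to derive (each from a distinct source ASV;
#'   core-enriched taxa are used as sources first, mimicking targeted
#'   culturing of responsive taxa).
#' @param divergence per-site substitution rate in [0, 0.2].
#' @param seed integer seed.
#' @param length_nt amplicon length.
#' @return list `asv` and `isolates` (named character vectors) and
#'   `pairing` (data.frame isolate_id, source_asv, n_substitutions,
#'   true_identity).
#' @export
generate_sequences <- function(truth, n_isolates, divergence = 0.01,
                               seed = 0L, length_nt = 420L) {
  if (divergence < 0 || divergence > 0.2)
    stop("divergence must lie in [0, 0.2]")
  if (inherits(truth, "planted_truth")) {
    asv_ids <- truth$taxa$taxon_id
    pref <- order(truth$taxa$status != "enriched")  # enriched sources first
  } else {
    asv_ids <- sprintf("ASV%04d", seq_len(as.integer(truth)))
    pref <- seq_along(asv_ids)
  }
  if (n_isolates > length(asv_ids))
    stop("n_isolates exceeds the number of ASVs")
  set.seed(derive_seed(seed, "sequences"))
  bases <- c("A", "C", "G", "T")
  asv <- vapply(asv_ids, function(id)
    paste(sample(bases, length_nt, replace = TRUE), collapse = ""),
    character(1))
  src <- asv_ids[pref[seq_len(n_isolates)]]
  iso_ids <- sprintf("ISO%03d", seq_len(n_isolates))
  n_sub <- stats::rbinom(n_isolates, length_nt, divergence)
  isolates <- character(n_isolates)
  for (k in seq_len(n_isolates)) {
    s <- strsplit(asv[[src[k]]], "")[[1]]
    if (n_sub[k] > 0) {
      pos <- sample(length_nt, n_sub[k])
      s[pos] <- vapply(s[pos],
                       function(b) sample(setdiff(bases, b), 1), character(1))
    }
    isolates[k] <- paste(s, collapse = "")
  }
  names(isolates) <- iso_ids
  list(asv = asv, isolates = isolates,
       pairing = data.frame(isolate_id = iso_ids, source_asv = src,
                            n_substitutions = n_sub,
                            true_identity = 1 - n_sub / length_nt,
                            stringsAsFactors = FALSE))
}

#' Generate screening phenotypes with known tolerance structure
#'
#' Shoot fresh weights: control plants draw from Normal(mu_e, cv * mu_e);
#' drought plants draw around the ecotype control mean scaled by the
#' soil-state tolerance factor recorded in the truth (`rfw_sterilized`,
#' `rfw_live`). Wilting scores (1-5 ordinal) map monotonically from the
#' live-soil tolerance factor with ordinal noise.
#'
#' @param truth a `planted_truth` from [generate_community()].
#' @param n_plants plants per (ecotype, treatment, soil state).
#' @param cv coefficient of variation of weights (0 gives deterministic
#'   weights).
#' @param seed integer seed.
#' @return `phenotype_table` data.frame: plant_id, ecotype, treatment,
#'   soil_state, fresh_weight_mg, wilting_score.
#' @export
generate_phenotypes <- function(truth, n_plants = 8, cv = 0.15, seed = 0L) {
  stopifnot(inherits(truth, "planted_truth"))
  set.seed(derive_seed(seed, "phenotypes"))
  eco <- truth$ecotypes
  mu <- stats::setNames(seq(120, 180, length.out = nrow(eco)), eco$ecotype)
  rows <- list()
  for (i in seq_len(nrow(eco))) {
    for (soil in c("live", "sterilized")) {
      factor_es <- if (soil == "live") eco$rfw_live[i] else
        eco$rfw_sterilized[i]
      for (tr in c("control", "drought")) {
        m <- if (tr == "control") mu[i] else mu[i] * factor_es
        w <- m * exp(stats::rnorm(n_plants, 0, cv))
        if (cv == 0) w <- rep(m, n_plants)
        score <- if (tr == "control") rep(5L, n_plants) else
          pmin(5L, pmax(1L, as.integer(round(
            1 + 4 * min(eco$rfw_live[i], 1) +
              stats::rnorm(n_plants, 0, if (cv == 0) 0 else 0.5)))))
        rows[[length(rows) + 1]] <- data.frame(
          plant_id = sprintf("%s_%s_%s_p%d", eco$ecotype[i], soil,
                             substr(tr, 1, 1), seq_len(n_plants)),
          ecotype = eco$ecotype[i], treatment = tr, soil_state = soil,
          fresh_weight_mg = w, wilting_score = score,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  phenotype_table(out)
}
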