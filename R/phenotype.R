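#' Phenotype table
#'
#' Per-plant screening measurements: shoot fresh weight (mg, > 0) and the
#' 1-5 ordinal wilting score (5 = no wilting, 4 = < 25% wilted leaves,
#' 3 = 25-50%, 2 = 50-75%, 1 = 75-90% wilted), under live or sterilized
#' soil and control or drought watering.
#'
#' @param df data.frame with columns `plant_id`, `ecotype`, `treatment`
#'   (`control`/`drought`), `soil_state` (`live`/`sterilized`),
#'   `fresh_weight_mg`, `wilting_score`.
#' @export
phenotype_table <- function(df) {
  need <- c("plant_id", "ecotype", "treatment", "soil_state",
            "fresh_weight_mg", "wilting_score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("phenotype table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$treatment %in% c("control", "drought")))
    stop("treatment must be control or drought")
  if (!all(df$soil_state %in% c("live", "sterilized")))
    stop("soil_state must be live or sterilized")
  if (any(df$fresh_weight_mg <= 0)) stop("fresh weights must be positive")
  if (!all(df$wilting_score %in% 1:5))
    stop("wilting scores must be integers 1..5")
  df <- df[, need]
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname phenotype_table
#' @param path TSV file path.
#' @export
read_phenotypes <- function(path) {
  phenotype_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname phenotype_table
#' @param x a `phenotype_table`.
#' @export
write_phenotypes <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Drought tolerance index of an ecotype
#'
#' Arithmetic mean of the wilting scores of drought-treated plants (higher
#' = more tolerant). [rank_tolerance()] ranks all ecotypes and returns the
#' top-k (most tolerant) and bottom-k (most sensitive) sets used to pick
#' contrasting ecotypes.
#'
#' @param p a [phenotype_table()].
#' @param ecotype ecotype name.
#' @param soil_state soil state to evaluate in (default live soil).
#' @export
tolerance_index <- function(p, ecotype, soil_state = "live") {
  stopifnot(inherits(p, "phenotype_table"))
  s <- p$wilting_score[p$ecotype == ecotype & p$treatment == "drought" &
                         p$soil_state == soil_state]
  if (length(s) == 0)
    stop("no drought plants for ecotype '", ecotype, "'")
  mean(s)
}

#' @rdname tolerance_index
#' @param k number of ecotypes per tail.
#' @export
rank_tolerance <- function(p, k = 5, soil_state = "live") {
  ecos <- unique(p$ecotype)
  idx <- vapply(ecos, function(e)
    tolerance_index(p, e, soil_state = soil_state), numeric(1))
  ord <- order(-idx, ecos)
  list(index = stats::setNames(idx, ecos)[ord],
       tolerant = ecos[ord][seq_len(min(k, length(ecos)))],
       sensitive = rev(ecos[ord])[seq_len(min(k, length(ecos)))])
}

#' Relative fresh weight under drought
#'
#' Each drought-treated plant's shoot fresh weight divided by the mean
#' control weight of the same ecotype and soil state: the fraction of
#' biomass retained under drought.
#'
#' @param p a [phenotype_table()].
#' @param ecotype ecotype name.
#' @param soil_state `"live"` or `"sterilized"`.
#' @return named numeric vector of per-plant ratios.
#' @export
relative_fresh_weight <- function(p, ecotype, soil_state = "live") {
  stopifnot(inherits(p, "phenotype_table"))
  sel <- p$ecotype == ecotype & p$soil_state == soil_state
  ctrl <- p$fresh_weight_mg[sel & p$treatment == "control"]
  drt <- p$fresh_weight_mg[sel & p$treatment == "drought"]
  if (length(ctrl) < 2)
    stop("ecotype '", ecotype, "' needs >= 2 control plants in ",
         soil_state, " soil")
  stats::setNames(drt / mean(ctrl),
                  p$plant_id[sel & p$treatment == "drought"])
}

#' Microbiome-mediated protection effect
#'
#' Mean relative fresh weight in live soil divided by the mean in
#' sterilized soil; values above 1 indicate the soil microbiome buffers
#' the ecotype against drought damage. `mode = "difference"` returns the
#' difference of the two means instead.
#'
#' @param p a [phenotype_table()].
#' @param ecotype ecotype name.
#' @param mode `"ratio"` (default) or `"difference"`.
#' @export
protection_effect <- function(p, ecotype, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  live <- mean(relative_fresh_weight(p, ecotype, "live"))
  ster <- mean(relative_fresh_weight(p, ecotype, "sterilized"))
  if (mode == "ratio") {
    if (ster == 0) stop("sterilized-soil relative fresh weight is 0")
    live / ster
  } else {
    live - ster
  }
}

#' @rdname protection_effect
#' @param k number of top ecotypes to return.
#' @export
rank_protection <- function(p, k = 5, mode = "ratio") {
  ecos <- unique(p$ecotype)
  eff <- vapply(ecos, function(e) protection_effect(p, e, mode = mode),
                numeric(1))
  ord <- order(-eff, ecos)
  list(effect = stats::setNames(eff, ecos)[ord],
       top = ecos[ord][seq_len(min(k, length(ecos)))])
}
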