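#' @keywords internal
"_PACKAGE"

#' Recognised taxonomic ranks, highest to lowest
#' @export
TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order",
                     "family", "genus", "species")

#' Sample metadata (study design)
#'
#' One row per sample: host ecotype, watering treatment, drought-tolerance
#' class of the ecotype and biological replicate number. Bulk-soil samples
#' use `tolerance_class = "bulk"` and are treated as their own "ecotype",
#' excluded from cross-ecotype core calling.
#'
#' @param df data.frame with columns `sample_id`, `ecotype`, `treatment`
#'   (`control`/`drought`), `tolerance_class` (`tolerant`/`sensitive`/`bulk`),
#'   `replicate` (integer >= 1).
#' @export
study_design <- function(df) {
  need <- c("sample_id", "ecotype", "treatment", "tolerance_class",
            "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("study design missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in study design")
  if (!all(df$treatment %in% c("control", "drought")))
    stop("treatment must be 'control' or 'drought'")
  if (!all(df$tolerance_class %in% c("tolerant", "sensitive", "bulk")))
    stop("tolerance_class must be tolerant, sensitive or bulk")
  if (!all(df$replicate == round(df$replicate) & df$replicate >= 1))
    stop("replicate must be a positive integer")
  df <- df[, need]
  df$replicate <- as.integer(df$replicate)
  class(df) <- c("study_design", "data.frame")
  df
}

#' @rdname study_design
#' @param x,t a `study_design` / [count_table()] pair to check against each
#'   other.
#' @export
check_design <- function(x, t) {
  stopifnot(inherits(x, "study_design"))
  miss <- setdiff(sample_ids(t), x$sample_id)
  if (length(miss) > 0)
    stop("samples without design rows: ", paste(miss, collapse = ", "))
  grp <- table(x$ecotype[x$sample_id %in% sample_ids(t)],
               x$treatment[x$sample_id %in% sample_ids(t)])
  if (any(grp > 0 & grp < 2))
    warning("some (ecotype, treatment) groups have < 2 replicates")
  invisible(x)
}

#' @rdname study_design
#' @param path TSV file path.
#' @export
read_study_design <- function(path) {
  study_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname study_design
#' @export
write_study_design <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Taxonomy table
#'
#' Maps taxon ids to the seven Linnean ranks. Unannotated ranks are stored
#' as `NA` (accepted input sentinels: `NA`, `""`, `"unclassified"`,
#' `"unassigned"`, or SILVA-style `"g__"` prefixes with empty names).
#'
#' @param df data.frame with column `taxon_id` plus rank columns
#'   `kingdom`..`species` (`species` optional).
#' @export
taxonomy_table <- function(df) {
  if (!"taxon_id" %in% names(df)) stop("taxonomy needs a 'taxon_id' column")
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon ids in taxonomy")
  need <- setdiff(TAXONOMIC_RANKS, "species")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("taxonomy missing ranks: ", paste(miss, collapse = ", "))
  if (!"species" %in% names(df)) df$species <- NA_character_
  df <- df[, c("taxon_id", TAXONOMIC_RANKS)]
  for (r in TAXONOMIC_RANKS) {
    v <- as.character(df[[r]])
    v <- sub("^[a-z]__", "", v)
    v[v %in% c("", "unclassified", "Unclassified", "unassigned",
               "Unassigned")] <- NA_character_
    df[[r]] <- v
  }
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' @rdname taxonomy_table
#' @param path TSV file path.
#' @export
read_taxonomy <- function(path) {
  taxonomy_table(utils::read.delim(path, stringsAsFactors = FALSE,
                                   colClasses = "character"))
}

#' @rdname taxonomy_table
#' @param x a `taxonomy_table`.
#' @export
write_taxonomy <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Deterministic display labels at a rank
#'
#' Annotated taxa get their rank name verbatim. Unannotated taxa get
#' `<lowest annotated parent>_<rank initial>` (e.g. an ASV with no genus but
#' family `Comamonadaceae` labels as `Comamonadaceae_g`), keeping
#' unannotated groups distinct by parentage rather than lumping them.
#' Taxa with no annotation at any rank label as `unclassified_<initial>`.
#'
#' @param tax a [taxonomy_table()].
#' @param rank rank name.
#' @return named character vector, taxon_id -> label.
#' @export
rank_labels <- function(tax, rank) {
  stopifnot(inherits(tax, "taxonomy_table"))
  if (!rank %in% TAXONOMIC_RANKS)
    stop("unknown rank '", rank, "'; expected one of: ",
         paste(TAXONOMIC_RANKS, collapse = ", "))
  i <- match(rank, TAXONOMIC_RANKS)
  lab <- as.character(tax[[rank]])
  if (any(is.na(lab))) {
    if (i == 1) {
      fallback <- rep("unclassified", nrow(tax))
    } else {
      parents <- as.matrix(as.data.frame(tax)[TAXONOMIC_RANKS[seq_len(i - 1)]])
      fallback <- apply(parents, 1L, function(row) {
        ann <- row[!is.na(row)]
        if (length(ann) == 0) "unclassified" else ann[[length(ann)]]
      })
    }
    lab[is.na(lab)] <- paste0(fallback[is.na(lab)], "_", substr(rank, 1, 1))
  }
  stats::setNames(lab, tax$taxon_id)
}
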