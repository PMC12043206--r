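#' ASV count table
#'
#' Central container of the pipeline: a non-negative integer matrix of read
#' counts with samples in rows and taxa (ASVs) in columns. The orientation is
#' fixed package-wide; files declare it through the header convention of
#' [write_count_table()].
#'
#' @param counts integer matrix, samples x taxa, with row and column names.
#' @return A `count_table`: an integer matrix with class attribute, validated
#'   so that ids are unique, counts are non-negative integers and every
#'   sample total is positive.
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' ct <- count_table(m)
#' sample_ids(ct)
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_table requires sample (row) and taxon (column) names")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid count at sample '%s', taxon '%s': %s",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])))
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  zero <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero) > 0)
    stop("samples with zero total counts: ", paste(zero, collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(counts, class = c("count_table", "matrix", "array"))
}

#' @rdname count_table
#' @param x object to test or query.
#' @export
is_count_table <- function(x) inherits(x, "count_table")

#' @rdname count_table
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname count_table
#' @export
taxon_ids <- function(x) colnames(x)

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read / write count tables
#'
#' TSV layout: header row of taxon ids, first column named `sample_id`
#' holding sample ids, one row per sample. BIOM-style JSON follows the
#' minimal dense BIOM 1.0 layout (`rows` = taxa, `columns` = samples,
#' `matrix_type` = "dense"), transposed on read to the package's
#' samples-in-rows convention.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return [read_count_table()] returns a validated [count_table()];
#'   [write_count_table()] returns `path` invisibly.
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2 || names(df)[1] != "sample_id")
      stop("TSV count table must start with a 'sample_id' column")
    m <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "numeric")
    if (anyNA(m)) {
      ij <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric count at sample '%s', taxon '%s'",
                   df$sample_id[ij[1]], colnames(m)[ij[2]]))
    }
    rownames(m) <- df$sample_id
    count_table(m)
  } else {
    b <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(b$rows) || is.null(b$columns) || is.null(b$data))
      stop("not a BIOM-style JSON table: ", path)
    taxa <- if (is.data.frame(b$rows)) b$rows$id else
      vapply(b$rows, `[[`, "", "id")
    samples <- if (is.data.frame(b$columns)) b$columns$id else
      vapply(b$columns, `[[`, "", "id")
    m <- matrix(0, nrow = length(taxa), ncol = length(samples),
                dimnames = list(taxa, samples))
    if (identical(b$matrix_type, "sparse")) {
      d <- if (is.matrix(b$data)) b$data else do.call(rbind, b$data)
      m[d[, 1:2, drop = FALSE] + 1L] <- d[, 3]
    } else {
      d <- if (is.matrix(b$data)) b$data else do.call(rbind, b$data)
      m[] <- d
    }
    count_table(t(m))
  }
}

#' @rdname read_count_table
#' @param x a [count_table()].
#' @export
write_count_table <- function(x, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  stopifnot(is_count_table(x))
  if (format == "tsv") {
    df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tm <- t(unclass(x))  # BIOM stores taxa as rows
    obj <- list(
      id = "count-table", format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table", generated_by = "coreresponder",
      date = "1970-01-01T00:00:00",
      matrix_type = "dense", matrix_element_type = "int",
      shape = dim(tm),
      rows = lapply(rownames(tm), function(id) list(id = id, metadata = NULL)),
      columns = lapply(colnames(tm),
                       function(id) list(id = id, metadata = NULL)),
      data = unname(lapply(seq_len(nrow(tm)), function(i) unname(tm[i, ]))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param t a [count_table()].
#' @return numeric matrix of the same shape with rows summing to 1, class
#'   `relative_abundance`.
#' @export
to_relative_abundance <- function(t) {
  m <- unclass(t)
  storage.mode(m) <- "double"
  tot <- rowSums(m)
  zero <- rownames(m)[tot == 0]
  if (length(zero) > 0)
    stop("samples with zero total: ", paste(zero, collapse = ", "))
  r <- m / tot
  structure(r, class = c("relative_abundance", "matrix", "array"))
}

#' Drop taxa observed in at most one sample
#'
#' Taxa with nonzero counts in no more than one sample carry no
#' co-occurrence or replication signal and are removed ahead of all
#' downstream stages. Idempotent; survivor order preserved.
#'
#' @param t a [count_table()].
#' @export
filter_singletons <- function(t) {
  stopifnot(is_count_table(t))
  prev <- colSums(unclass(t) > 0)
  count_table(unclass(t)[, prev >= 2, drop = FALSE])
}

#' Aggregate counts to a taxonomic rank
#'
#' Counts are summed over taxa sharing the rank label produced by
#' [rank_labels()], so unannotated taxa stay separated by their lowest
#' annotated parent (e.g. genus-less ASVs of family `Oxalobacteraceae`
#' aggregate under `Oxalobacteraceae_g`, distinct from any named genus).
#'
#' @param t a [count_table()].
#' @param tax a taxonomy table from [taxonomy_table()].
#' @param rank one of `r TAXONOMIC_RANKS`.
#' @export
aggregate_to_rank <- function(t, tax, rank) {
  stopifnot(is_count_table(t))
  lab <- rank_labels(tax, rank)
  missing_tax <- setdiff(taxon_ids(t), names(lab))
  if (length(missing_tax) > 0)
    stop("taxa missing from taxonomy: ", paste(missing_tax, collapse = ", "))
  g <- factor(lab[taxon_ids(t)], levels = unique(lab[taxon_ids(t)]))
  agg <- t(rowsum(t(unclass(t)), group = g))
  count_table(agg)
}
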