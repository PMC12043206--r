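#' Sequence records
#'
#' Thin named-character representation of 16S V3-V4 amplicon sequences:
#' uppercased, U normalised to T, alphabet restricted to A/C/G/T/N.
#'
#' @param x named character vector of sequences.
#' @return validated named character vector of class `sequence_set`.
#' @export
sequence_set <- function(x) {
  if (is.null(names(x)) || any(names(x) == ""))
    stop("sequences must be named")
  if (anyDuplicated(names(x))) stop("duplicate sequence ids")
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  if (any(nchar(x) == 0)) stop("empty sequence")
  if (any(grepl("[^ACGTN]", x)))
    stop("sequences may only contain A, C, G, T, N")
  structure(x, class = "sequence_set")
}

#' @rdname sequence_set
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  sequence_set(stats::setNames(as.character(s),
                               sub("\\s.*$", "", names(s))))
}

#' @rdname sequence_set
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(x)), path, width = 80L)
  invisible(path)
}

# substitution matrix over the amplicon alphabet: N never matches anything
.sub_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      bases <- c("A", "C", "G", "T", "N")
      mm <- matrix(-1, 5, 5, dimnames = list(bases, bases))
      diag(mm) <- 1
      mm["N", "N"] <- -1
      m <<- mm
    }
    m
  }
})

#' Pairwise percent identity
#'
#' Default (`mode = "global"`): Needleman-Wunsch alignment of both full
#' sequences with match +1, mismatch -1, gap -2 per gap column, identity =
#' identical columns / aligned columns after excluding terminal-gap
#' columns, the convention of conventional amplicon clustering tools. `N`
#' never counts as a match and internal gaps count as non-matching
#' columns.
#'
#' `mode = "overlap"` scores end gaps as free and computes identity over
#' the best-scoring overlap region only. Beware that on unrelated
#' sequences the optimal ends-free overlap degenerates to a short
#' high-identity window, inflating identity; it is offered for genuinely
#' trimming-shifted amplicons, not as a matching default.
#'
#' @param a,b sequences (plain strings).
#' @param mode `"global"` (default) or `"overlap"`.
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b, mode = c("global", "overlap")) {
  mode <- match.arg(mode)
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = if (mode == "overlap") "overlap" else "global",
    substitutionMatrix = .sub_matrix(),
    gapOpening = 0, gapExtension = 2)
  if (mode == "overlap") {
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  } else {
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    # trim terminal-gap columns
    gap <- pa == "-" | pb == "-"
    first <- match(FALSE, gap)
    last <- length(gap) + 1L - match(FALSE, rev(gap))
    if (is.na(first)) return(0)
    keep <- seq(first, last)
    pa <- pa[keep]; pb <- pb[keep]
  }
  cols <- length(pa)
  if (cols == 0) return(0)
  matches <- sum(pa == pb & pa %in% c("A", "C", "G", "T"))
  matches / cols
}

# identities of one query against many references in a single vectorised
# alignment call; same scoring/denominator as pairwise_identity()
.identity_to_refs <- function(query, refs, mode = "global") {
  if (length(refs) == 0) return(numeric(0))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(refs), Biostrings::DNAString(query),
    type = if (mode == "overlap") "overlap" else "global",
    substitutionMatrix = .sub_matrix(),
    gapOpening = 0, gapExtension = 2)
  # fast path: for N-free global alignments of near-full-length amplicons
  # nmatch/nchar equals the string-based identity (terminal-gap columns do
  # not arise with penalised end gaps on same-scale sequences)
  if (mode == "global" && !grepl("N", query, fixed = TRUE) &&
      !any(grepl("N", refs, fixed = TRUE))) {
    return(stats::setNames(
      Biostrings::nmatch(aln) / Biostrings::nchar(aln), names(refs)))
  }
  if (mode == "overlap") {
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "")
    pb <- strsplit(as.character(Biostrings::subject(aln)), "")
  } else {
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")
    pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")
  }
  out <- numeric(length(refs))
  for (k in seq_along(refs)) {
    a <- pa[[k]]; b <- pb[[k]]
    if (mode != "overlap") {
      gap <- a == "-" | b == "-"
      first <- match(FALSE, gap)
      if (is.na(first)) { out[k] <- 0; next }
      last <- length(gap) + 1L - match(FALSE, rev(gap))
      a <- a[first:last]; b <- b[first:last]
    }
    out[k] <- if (length(a) == 0) 0 else
      sum(a == b & a %in% c("A", "C", "G", "T")) / length(a)
  }
  stats::setNames(out, names(refs))
}

#' Dereplicate and greedily cluster sequences at an identity threshold
#'
#' Exact duplicates are collapsed first with size accumulation. Unique
#' sequences are then processed in decreasing size order (ties broken by
#' id): each joins the best-identity existing centroid at
#' identity >= `id_min` (inclusive boundary), otherwise founds a new
#' cluster whose representative it becomes — the greedy centroid scheme of
#' conventional 97% OTU pickers.
#'
#' @param seqs a [sequence_set()] (or named character vector) of isolate
#'   sequences.
#' @param id_min identity threshold (0.97 reproduces 97% OTUs).
#' @param mode identity mode passed to [pairwise_identity()].
#' @return list of class `otu_clustering`: `clusters` (data.frame:
#'   sequence_id, cluster, representative, identity_to_rep, size),
#'   `representatives` (named character), `sizes` (named integer, per
#'   cluster).
#' @export
dereplicate_and_cluster <- function(seqs, id_min = 0.97,
                                    mode = "global") {
  seqs <- sequence_set(unclass(seqs))
  if (length(seqs) == 0) stop("need at least one sequence")
  # dereplicate: identical strings collapse onto the first id
  first_id <- tapply(names(seqs), unclass(seqs),
                     function(v) sort(v)[1])
  sizes <- tapply(names(seqs), unclass(seqs), length)
  uniq <- stats::setNames(names(first_id), first_id)  # id -> sequence
  usize <- stats::setNames(as.integer(sizes), first_id)
  member_of <- stats::setNames(first_id[unclass(seqs)], names(seqs))
  ord <- order(-usize[names(uniq)], names(uniq))
  ids <- names(uniq)[ord]
  rep_ids <- character(0)
  assign_rep <- character(0)
  assign_idy <- numeric(0)
  for (id in ids) {
    if (length(rep_ids) == 0) {
      rep_ids <- id
      assign_rep[id] <- id; assign_idy[id] <- 1
      next
    }
    idy <- .identity_to_refs(uniq[[id]],
                             stats::setNames(as.character(uniq[rep_ids]),
                                             rep_ids), mode = mode)
    best <- which.max(idy)
    if (idy[best] >= id_min) {
      assign_rep[id] <- rep_ids[best]; assign_idy[id] <- idy[best]
    } else {
      rep_ids <- c(rep_ids, id)
      assign_rep[id] <- id; assign_idy[id] <- 1
    }
  }
  cluster_of <- stats::setNames(match(assign_rep, rep_ids), names(assign_rep))
  clusters <- data.frame(
    sequence_id = names(seqs),
    cluster = as.integer(cluster_of[member_of[names(seqs)]]),
    representative = assign_rep[member_of[names(seqs)]],
    identity_to_rep = as.numeric(assign_idy[member_of[names(seqs)]]),
    stringsAsFactors = FALSE, row.names = NULL)
  csize <- table(clusters$cluster)
  clusters$size <- as.integer(csize[as.character(clusters$cluster)])
  structure(list(
    clusters = clusters,
    representatives = stats::setNames(as.character(uniq[rep_ids]), rep_ids),
    sizes = stats::setNames(as.integer(csize), rep_ids)),
    class = "otu_clustering")
}

#' Match ASVs against cluster representatives
#'
#' Each ASV is aligned to every representative; the best-identity hit wins,
#' with ties broken by larger cluster size then lexicographic id. An ASV is
#' `matched` when the best identity reaches `id_min`.
#'
#' @param asvs ASV sequences ([sequence_set()] or named character).
#' @param clustering an `otu_clustering` from [dereplicate_and_cluster()],
#'   or a named character vector of representative sequences.
#' @param id_min identity threshold for a successful match.
#' @param mode identity mode passed to [pairwise_identity()].
#' @return data.frame of class `match_report`: asv, best_hit, identity,
#'   matched.
#' @export
match_asvs <- function(asvs, clustering, id_min = 0.97,
                       mode = "global") {
  asvs <- sequence_set(unclass(asvs))
  if (inherits(clustering, "otu_clustering")) {
    reps <- clustering$representatives
    sizes <- clustering$sizes
  } else {
    reps <- unclass(sequence_set(unclass(clustering)))
    sizes <- stats::setNames(rep(1L, length(reps)), names(reps))
  }
  if (length(asvs) == 0 || length(reps) == 0)
    stop("both ASV and representative sets must be non-empty")
  rows <- lapply(names(asvs), function(a) {
    idy <- .identity_to_refs(asvs[[a]], reps, mode = mode)
    ord <- order(-idy, -as.integer(sizes[names(reps)]), names(reps))
    best <- ord[1]
    data.frame(asv = a, best_hit = names(reps)[best],
               identity = idy[best], matched = idy[best] >= id_min,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("match_report", "data.frame"))
}
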