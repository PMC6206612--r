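#' Scoring scheme for percent-identity alignments
#'
#' Global-alignment scoring used when computing pairwise identity for
#' clustering. The defaults (match +2, mismatch -4, gap open -10, gap extend
#' -1, with the first gap base charged the opening penalty) strongly
#' discourage gaps, matching how centroid clusterers of near-identical
#' amplicons behave.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores; `match > 0 >
#'   mismatch`, gap penalties non-positive.
#' @return a validated scoring list.
#' @export
identity_scheme <- function(match = 2, mismatch = -4, gap_open = -10,
                            gap_extend = -1) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Exact dereplication with abundance sorting
#'
#' Collapses identical sequence strings, tracking abundance and member read
#' identifiers. Entries are sorted by descending abundance, ties broken
#' lexicographically by sequence.
#'
#' @param seqs character vector of sequences, or a FASTQ record data frame.
#' @param ids read identifiers (defaults to the record ids or names).
#' @return A data frame with columns `seq`, `abundance`, and list-column
#'   `member_ids`; first member id doubles as the dereplicated entry's id.
#' @export
dereplicate_exact <- function(seqs, ids = NULL) {
  if (is.data.frame(seqs)) {
    if (is.null(ids)) ids <- seqs$id
    seqs <- seqs$seq
  }
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  stopifnot(length(seqs) == length(ids))
  if (!length(seqs)) {
    out <- data.frame(seq = character(), abundance = integer(),
                      stringsAsFactors = FALSE)
    out$member_ids <- list()
    return(out)
  }
  groups <- split(ids, factor(seqs, levels = unique(seqs)))
  out <- data.frame(seq = names(groups),
                    abundance = lengths(groups, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out$member_ids <- unname(groups)
  ord <- order(-out$abundance, out$seq)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise percent identity from an optimal global alignment
#'
#' Identity is the number of matching columns divided by the total number of
#' alignment columns of an optimal affine-gap global alignment; gap columns
#' (terminal gaps included) count in the denominator and `N` never matches.
#'
#' @param a,b non-empty DNA strings.
#' @param scheme alignment scores from [identity_scheme()].
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, scheme = identity_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity: empty sequence")
  .pairwise_identity_cpp(a, b, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend)
}

#' Greedy abundance-ordered centroid clustering
#'
#' Scans dereplicated sequences in descending-abundance order. Each sequence
#' joins the first existing cluster (in representative creation order) whose
#' representative is at least `threshold` identical to it, otherwise it
#' founds a new cluster with itself as representative. At `threshold = 1`
#' the clustering equals exact dereplication. A shared 8-mer count bound
#' screens representatives before the full alignment; the bound is lossless
#' at the permitted thresholds and can be disabled.
#'
#' @param uniques data frame from [dereplicate_exact()] (already sorted).
#' @param threshold identity threshold in `[0.98, 1.00]` (default 0.995).
#' @param scheme alignment scores from [identity_scheme()].
#' @param use_prefilter logical; disable to force a full alignment against
#'   every candidate representative.
#' @return `uniques` with an integer `cluster` column (1-based, in
#'   representative creation order) and attribute `representatives`, the row
#'   indices of cluster representatives.
#' @export
cluster_greedy <- function(uniques, threshold = 0.995,
                           scheme = identity_scheme(), use_prefilter = TRUE) {
  if (threshold < 0.98 || threshold > 1.00) {
    stop("identity threshold must be within [0.98, 1.00], got ", threshold)
  }
  assign <- .greedy_cluster_cpp(uniques$seq, threshold, scheme$match,
                                scheme$mismatch, scheme$gap_open,
                                scheme$gap_extend, 8L, use_prefilter)
  uniques$cluster <- assign
  attr(uniques, "representatives") <- match(seq_len(max(assign, 0L)), assign)
  attr(uniques, "identity_threshold") <- threshold
  uniques
}

#' Cluster membership map
#'
#' @param clustered output of [cluster_greedy()].
#' @return A data frame with one row per read: `read_id`,
#'   `representative_id`, `cluster_index`.
#' @export
cluster_map <- function(clustered) {
  reps <- attr(clustered, "representatives")
  rep_id <- vapply(clustered$member_ids[reps], `[[`, character(1), 1L)
  n_mem <- lengths(clustered$member_ids)
  data.frame(read_id = unlist(clustered$member_ids, use.names = FALSE),
             representative_id = rep(rep_id[clustered$cluster], n_mem),
             cluster_index = rep(clustered$cluster, n_mem),
             stringsAsFactors = FALSE)
}
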