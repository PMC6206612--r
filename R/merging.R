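#' Merge parameters
#'
#' Parameters of the overlap-based pair merger. The cited merging stage does
#' not publish its settings, so these defaults are this package's own:
#' a minimum overlap of 12 bases, at most 25% mismatches in the overlap, and
#' consensus qualities capped at Phred 41 (the Illumina 1.8+ maximum).
#'
#' @param min_overlap minimum acceptable overlap length in bases (>= 4).
#' @param max_mismatch_rate maximum fraction of mismatching overlap columns,
#'   in `[0, 0.5)`.
#' @param quality_cap maximum consensus Phred score.
#' @return A list of validated merge parameters.
#' @export
merge_params <- function(min_overlap = 12L, max_mismatch_rate = 0.25,
                         quality_cap = 41L) {
  stopifnot(min_overlap >= 4L, max_mismatch_rate >= 0, max_mismatch_rate < 0.5,
            quality_cap >= 2L, quality_cap <= 93L)
  list(min_overlap = as.integer(min_overlap),
       max_mismatch_rate = max_mismatch_rate,
       quality_cap = as.integer(quality_cap))
}

#' Reverse-complement DNA strings
#'
#' @param seq character vector over `A,C,G,T,N`.
#' @return reverse complements.
#' @export
revcomp <- function(seq) {
  if (!length(seq)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Find the best overlap between a read pair
#'
#' The reverse read is reverse-complemented, then all overlap placements with
#' length at least `min_overlap` are scanned in both the normal geometry
#' (insert at least as long as the reads) and the read-through geometry
#' (insert shorter than the reads, overhangs to be clipped). Among placements
#' whose mismatch rate does not exceed `max_mismatch_rate`, the one with the
#' most matching bases wins; ties go to the longer overlap. `N` never counts
#' as a match.
#'
#' @param forward,reverse one-row FASTQ record data frames (see
#'   [fastq_records()]); `reverse` is in raw (instrument) orientation.
#' @param params merge parameters from [merge_params()].
#' @return overlap length as an integer, or `NULL` when no placement
#'   qualifies (absence of overlap is a value, not an error).
#' @export
find_overlap <- function(forward, reverse, params = merge_params()) {
  rc <- revcomp(reverse$seq)
  res <- .find_overlap_cpp(forward$seq, rc, params$min_overlap,
                           params$max_mismatch_rate)
  if (is.na(res$overlap)) NULL else res$overlap
}

#' Merge one read pair into a consensus record
#'
#' In the overlap, agreeing positions keep the base with quality
#' `min(q1 + q2, quality_cap)`; disagreeing positions keep the base with the
#' higher quality and quality `|q1 - q2|` (quality ties keep the forward base
#' with quality 2; an `N` never wins). Outside the overlap, bases and
#' qualities are copied from their source read. The merged record keeps the
#' forward read's identifier and description.
#'
#' @inheritParams find_overlap
#' @return A one-row record data frame with extra columns `overlap_length`
#'   and `source_id`, or `NULL` if the pair cannot be merged.
#' @export
merge_pair <- function(forward, reverse, params = merge_params()) {
  rc <- revcomp(reverse$seq)
  rq <- rev_string(reverse$qual)
  res <- .merge_pair_cpp(forward$seq, forward$qual, rc, rq,
                         params$min_overlap, params$max_mismatch_rate,
                         params$quality_cap)
  if (is.null(res$merged)) return(NULL)
  out <- fastq_records(forward$id, res$merged, res$qual, forward$desc)
  out$overlap_length <- res$overlap
  out$source_id <- forward$id
  out
}

rev_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Merge a stream of read pairs
#'
#' Unmergeable pairs are counted and their identifiers returned, never
#' silently dropped.
#'
#' @param pairs `list(forward = records, reverse = records)`.
#' @param params merge parameters from [merge_params()].
#' @return `list(merged = records, unmerged_ids = character, n_input = int)`.
#' @export
merge_pairs <- function(pairs, params = merge_params()) {
  check_pairing(pairs$forward, pairs$reverse)
  n <- nrow(pairs$forward)
  rc <- revcomp(pairs$reverse$seq)
  rq <- rev_string(pairs$reverse$qual)
  seqs <- character(n); quals <- character(n)
  overlaps <- integer(n); ok <- logical(n)
  for (i in seq_len(n)) {
    res <- .merge_pair_cpp(pairs$forward$seq[i], pairs$forward$qual[i],
                           rc[i], rq[i], params$min_overlap,
                           params$max_mismatch_rate, params$quality_cap)
    if (!is.null(res$merged)) {
      ok[i] <- TRUE
      seqs[i] <- res$merged; quals[i] <- res$qual; overlaps[i] <- res$overlap
    }
  }
  merged <- fastq_records(pairs$forward$id[ok], seqs[ok], quals[ok],
                          pairs$forward$desc[ok])
  merged$overlap_length <- overlaps[ok]
  merged$source_id <- merged$id
  list(merged = merged,
       unmerged_ids = pairs$forward$id[!ok],
       n_input = n)
}
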