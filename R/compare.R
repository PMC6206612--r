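#' Scoring scheme for trim-agreement alignments
#'
#' Defaults are the settings conventionally used for trimmer-agreement
#' comparisons of amplicon reads: match +2, mismatch
#' -1, gap opening -0.5, gap extension -0.1. The opening penalty is charged
#' on the first base of a gap and the extension penalty on each subsequent
#' base (so a length-1 gap costs 0.5, a length-2 gap 0.6).
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores; requires
#'   `match > 0 > mismatch` and non-positive gap penalties.
#' @return a validated scoring list.
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap_open = -0.5,
                           gap_extend = -0.1) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Optimal global alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment under the affine convention of
#' [scoring_scheme()]. Traceback tie-breaking is deterministic:
#' match/mismatch is preferred over a gap in `a`, which is preferred over a
#' gap in `b`.
#'
#' @param a,b non-empty DNA strings.
#' @param scheme scores from [scoring_scheme()].
#' @return `list(score, a_aln, b_aln)` with `-` marking gaps.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("global_align: empty sequence")
  .global_align_cpp(a, b, scheme$match, scheme$mismatch, scheme$gap_open,
                    scheme$gap_extend)
}

#' Start/stop offsets implied by a pairwise alignment
#'
#' For two trimmings of the same source read, the start offset is the
#' alignment-column difference of the first aligned base of `b` minus that
#' of `a` (positive when `b` starts later), and the stop offset the same
#' difference at the last aligned base.
#'
#' @param a_aln,b_aln aligned strings from [global_align()].
#' @return `c(start_offset, stop_offset)` in bases.
#' @export
alignment_offsets <- function(a_aln, b_aln) {
  av <- strsplit(a_aln, "")[[1]] != "-"
  bv <- strsplit(b_aln, "")[[1]] != "-"
  c(start_offset = which(bv)[1] - which(av)[1],
    stop_offset = max(which(bv)) - max(which(av)))
}

#' Compare two trimmings of the same read set
#'
#' Reads present in both sets with identical sequences get offsets (0, 0)
#' without aligning; differing reads are globally aligned and their start
#' and stop offsets computed from the alignment. The summary reports the
#' fraction of compared reads whose larger absolute offset is within
#' `window` bases (and at windows 0, 1, 2, 5), mirroring the within-2-bases
#' agreement metric used for trimmed amplicon sets.
#'
#' @param set_a,set_b FASTQ record data frames keyed by `id`.
#' @param window agreement window in bases.
#' @param scheme scores from [scoring_scheme()].
#' @return `list(comparisons, summary, only_a, only_b)`; `comparisons` has
#'   one row per shared read (`read_id`, `start_offset`, `stop_offset`,
#'   `identical`), `summary` the counts and agreement fractions.
#' @export
compare_trim_sets <- function(set_a, set_b, window = 2L,
                              scheme = scoring_scheme()) {
  if (anyDuplicated(set_a$id)) stop("duplicate read ids in set A")
  if (anyDuplicated(set_b$id)) stop("duplicate read ids in set B")
  common <- intersect(set_a$id, set_b$id)
  only_a <- setdiff(set_a$id, set_b$id)
  only_b <- setdiff(set_b$id, set_a$id)
  a <- set_a$seq[match(common, set_a$id)]
  b <- set_b$seq[match(common, set_b$id)]
  n <- length(common)
  so <- integer(n); eo <- integer(n)
  same <- a == b
  for (i in which(!same)) {
    # optimal alignments can tie; aligning in a canonical orientation (and
    # negating when swapped) keeps A-vs-B exactly the negation of B-vs-A
    if (a[i] <= b[i]) {
      aln <- global_align(a[i], b[i], scheme)
      off <- alignment_offsets(aln$a_aln, aln$b_aln)
    } else {
      aln <- global_align(b[i], a[i], scheme)
      off <- -alignment_offsets(aln$a_aln, aln$b_aln)
    }
    so[i] <- off[1]; eo[i] <- off[2]
  }
  comparisons <- data.frame(read_id = common, start_offset = so,
                            stop_offset = eo, identical = same,
                            stringsAsFactors = FALSE)
  maxoff <- pmax(abs(so), abs(eo))
  windows <- sort(unique(c(0L, 1L, 2L, 5L, as.integer(window))))
  frac <- vapply(windows, function(w) mean(maxoff <= w), numeric(1))
  list(comparisons = comparisons,
       summary = list(n_common = n, n_only_a = length(only_a),
                      n_only_b = length(only_b),
                      n_identical = sum(same),
                      window = as.integer(window),
                      fraction_within = mean(maxoff <= window),
                      fraction_by_window = setNames(frac, windows)),
       only_a = only_a, only_b = only_b)
}

#' Write a one-page trim-comparison report
#'
#' @param cmp result of [compare_trim_sets()].
#' @param path output text file; a TSV of per-read comparisons is written
#'   next to it with suffix `.tsv`.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(cmp, path) {
  s <- cmp$summary
  lines <- c(
    "trim comparison report",
    "======================",
    sprintf("reads compared:        %d", s$n_common),
    sprintf("  identical:           %d", s$n_identical),
    sprintf("only in set A:         %d", s$n_only_a),
    sprintf("only in set B:         %d", s$n_only_b),
    "",
    "agreement (max |start offset|, |stop offset| <= window):",
    sprintf("  window %s: %.4f%%", names(s$fraction_by_window),
            100 * s$fraction_by_window))
  writeLines(lines, path)
  write.table(cmp$comparisons, paste0(path, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
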