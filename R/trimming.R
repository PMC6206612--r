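#' Trim one FASTQ record to a half-open interval
#'
#' Sequence and quality are sliced identically; identifier and description
#' are unchanged. The caller must pre-clip: violated preconditions are an
#' internal error.
#'
#' @param record one-row FASTQ record data frame.
#' @param start,stop 0-based half-open coordinates, `0 <= start < stop <=
#'   length`.
#' @return the trimmed record.
#' @export
trim_record <- function(record, start, stop) {
  len <- nchar(record$seq)
  if (!(start >= 0 && start < stop && stop <= len)) {
    stop("internal error: trim interval [", start, ", ", stop,
         ") invalid for record '", record$id, "' of length ", len)
  }
  record$seq <- substr(record$seq, start + 1L, stop)
  record$qual <- substr(record$qual, start + 1L, stop)
  record
}

#' Propagate a representative's boundary call to its whole cluster
#'
#' The representative's `(start, stop)` are applied unmodified to every
#' member read — no re-alignment, which is precisely why insertions or
#' deletions between a member and its representative shift trim points
#' while substitutions do not. `stop` is clipped to each member's length;
#' members whose clipped interval is empty are excluded.
#'
#' @param member_ids character vector of read identifiers in the cluster.
#' @param member_lengths integer vector of the members' read lengths.
#' @param call boundary call for the cluster representative (one-row data
#'   frame from [call_boundaries()]), or `NULL` if the representative had
#'   no usable flank hit.
#' @return A data frame of trim outcomes: `read_id`, `status` (one of
#'   `trimmed`, `excluded_no_hit`, `excluded_empty`), `start`, `stop`.
#' @export
propagate_trim <- function(member_ids, member_lengths, call) {
  n <- length(member_ids)
  stopifnot(length(member_lengths) == n)
  if (is.null(call)) {
    return(data.frame(read_id = member_ids, status = rep("excluded_no_hit", n),
                      start = NA_integer_, stop = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  start <- call$start
  stop_ <- pmin.int(call$stop, member_lengths)
  empty <- stop_ <= start
  data.frame(read_id = member_ids,
             status = ifelse(empty, "excluded_empty", "trimmed"),
             start = ifelse(empty, NA_integer_, as.integer(start)),
             stop = ifelse(empty, NA_integer_, as.integer(stop_)),
             stringsAsFactors = FALSE)
}

#' Apply trim outcomes to records
#'
#' @param records FASTQ record data frame (original read order).
#' @param outcomes outcome data frame from [propagate_trim()] (any order).
#' @return `list(trimmed = records, excluded = records, outcomes = df)`;
#'   both record sets preserve the input order of `records`, and excluded
#'   records carry the exclusion reason appended to their description.
#' @export
apply_trim <- function(records, outcomes) {
  m <- match(records$id, outcomes$read_id)
  if (anyNA(m)) {
    stop("no trim outcome for record(s): ",
         paste(head(records$id[is.na(m)], 3), collapse = ", "))
  }
  st <- outcomes$status[m]
  keep <- st == "trimmed"
  trimmed <- records[keep, , drop = FALSE]
  if (nrow(trimmed)) {
    start <- outcomes$start[m][keep]
    stop_ <- outcomes$stop[m][keep]
    trimmed$seq <- substr(trimmed$seq, start + 1L, stop_)
    trimmed$qual <- substr(trimmed$qual, start + 1L, stop_)
  }
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded)) {
    tag <- paste0("itstrim_excluded=", st[!keep])
    excluded$desc <- ifelse(nzchar(excluded$desc),
                            paste(excluded$desc, tag), tag)
  }
  rownames(trimmed) <- rownames(excluded) <- NULL
  list(trimmed = trimmed, excluded = excluded, outcomes = outcomes)
}
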