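REGION_FLANKS <- list(
  ITS1 = c(left = "SSU_tail", right = "R5.8S"),
  ITS2 = c(left = "R5.8S", right = "LSU_head"),
  ALL  = c(left = "SSU_tail", right = "LSU_head")
)

#' Convert flank hits into ITS trim coordinates
#'
#' The ITS1 spacer runs from the end of the SSU tail to the start of the
#' 5.8S gene; ITS2 from the end of 5.8S to the start of the LSU head; ALL
#' from the end of the SSU tail to the start of the LSU head. When several
#' hits exist for one profile, the highest bit score wins (ties: leftmost on
#' the read). A missing left (right) flank falls back to the read start
#' (end) with its found-flag set to `FALSE`; if neither relevant flank was
#' found, or the resulting interval is empty, the read is excluded and
#' `NULL` is returned.
#'
#' @param hits data frame of hits as returned by [viterbi_local()] (may be
#'   `NULL` or empty).
#' @param region `"ITS1"`, `"ITS2"` or `"ALL"`.
#' @param read_length length of the read the hits refer to.
#' @param seq_id identifier stored in the call.
#' @return A one-row data frame (`seq_id`, `region`, `start`, `stop`,
#'   `left_flank_found`, `right_flank_found`), or `NULL`.
#' @export
call_boundaries <- function(hits, region = c("ITS1", "ITS2", "ALL"),
                            read_length, seq_id = "") {
  region <- match.arg(region)
  flanks <- REGION_FLANKS[[region]]
  left <- best_hit(hits, flanks[["left"]])
  right <- best_hit(hits, flanks[["right"]])
  if (is.null(left) && is.null(right)) return(NULL)
  start <- if (is.null(left)) 0L else left$seq_end
  stop_ <- if (is.null(right)) read_length else right$seq_start
  if (stop_ <= start) return(NULL)
  data.frame(seq_id = seq_id, region = region,
             start = as.integer(start), stop = as.integer(stop_),
             left_flank_found = !is.null(left),
             right_flank_found = !is.null(right),
             stringsAsFactors = FALSE)
}

best_hit <- function(hits, profile_name) {
  if (is.null(hits) || !nrow(hits)) return(NULL)
  h <- hits[hits$profile == profile_name, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h <- h[order(-h$bit_score, h$seq_start), , drop = FALSE]
  h[1, , drop = FALSE]
}

#' Parse a HMMER3 per-domain table (domtblout)
#'
#' Reads the standard whitespace-delimited `--domtblout` format and converts
#' the 1-based inclusive envelope coordinates (`env from`/`env to`) to
#' 0-based half-open `seq_start`/`seq_end`. Query (profile) names can be
#' mapped to the package's flank names via `profile_map`.
#'
#' @param path domtblout text file.
#' @param profile_map named character vector mapping file profile names to
#'   flank names, e.g. `c(my58S = "R5.8S")`; unmapped names pass through.
#' @return A data frame of hits with columns `profile`, `seq_id`,
#'   `seq_start`, `seq_end`, `profile_start`, `profile_end`, `bit_score`,
#'   `e_value`.
#' @export
parse_domtblout <- function(path, profile_map = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  out <- list()
  for (ln in which(keep)) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 22L) {
      stop("malformed domtblout line ", ln, " in ", path,
           ": expected >= 22 fields, got ", length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(13, 14, 16, 17, 20, 21)]))
    if (anyNA(num)) stop("malformed domtblout line ", ln, " in ", path,
                         ": non-numeric score or coordinate field")
    prof <- f[4]
    if (!is.null(profile_map) && prof %in% names(profile_map)) {
      prof <- unname(profile_map[[prof]])
    }
    out[[length(out) + 1L]] <- data.frame(
      profile = prof, seq_id = f[1],
      seq_start = as.integer(num[5]) - 1L, seq_end = as.integer(num[6]),
      profile_start = as.integer(num[3]) - 1L, profile_end = as.integer(num[4]),
      bit_score = num[2], e_value = num[1],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(profile = character(), seq_id = character(),
                      seq_start = integer(), seq_end = integer(),
                      profile_start = integer(), profile_end = integer(),
                      bit_score = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write hits as a HMMER3-style per-domain table
#'
#' Produces a minimal but standard-shaped domtblout file (comment header,
#' 23 whitespace-separated columns, 1-based inclusive envelope coordinates)
#' that [parse_domtblout()] reads back unchanged.
#'
#' @param hits data frame of hits (as from [viterbi_local()] or
#'   [parse_domtblout()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
    con)
  for (i in seq_len(NROW(hits))) {
    h <- hits[i, ]
    ali_from <- if ("ali_from" %in% names(hits)) h$ali_from + 1L else h$seq_start + 1L
    ali_to <- if ("ali_to" %in% names(hits)) h$ali_to else h$seq_end
    writeLines(sprintf(
      "%-20s -          %5d %-20s -          %5d %s %s   0.0   1   1 %s %s %s   0.0 %5d %5d %5d %5d %5d %5d 0.99 -",
      h$seq_id, h$seq_end - h$seq_start, h$profile,
      h$profile_end - h$profile_start,
      format(h$e_value, digits = 15), format(h$bit_score, digits = 15),
      format(h$e_value, digits = 15), format(h$e_value, digits = 15),
      format(h$bit_score, digits = 15),
      h$profile_start + 1L, h$profile_end, ali_from, ali_to,
      h$seq_start + 1L, h$seq_end), con)
  }
  invisible(path)
}
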