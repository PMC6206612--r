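#' Construct a table of FASTQ records
#'
#' Records are kept in a plain data frame with one row per read and columns
#' `id` (identifier up to the first whitespace, without the leading `@`),
#' `desc` (remainder of the header line, possibly empty), `seq` (DNA over
#' `A,C,G,T,N`) and `qual` (Phred+33 string, same length as `seq`).
#'
#' @param id character vector of identifiers.
#' @param seq character vector of DNA sequences.
#' @param qual character vector of Phred+33 quality strings.
#' @param desc character vector of header descriptions (default empty).
#' @return A validated `data.frame` of FASTQ records.
#' @export
fastq_records <- function(id, seq, qual, desc = "") {
  x <- data.frame(id = as.character(id), desc = rep_len(as.character(desc), length(id)),
                  seq = as.character(seq), qual = as.character(qual),
                  stringsAsFactors = FALSE)
  validate_fastq_records(x)
  x
}

#' Validate FASTQ record invariants
#'
#' Checks identifier form, sequence alphabet, equal sequence/quality lengths
#' and the printable Phred+33 quality range (ordinals 33-126).
#'
#' @param x a data frame as returned by [fastq_records()].
#' @return `x`, invisibly; errors name the first offending record.
#' @export
validate_fastq_records <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "desc", "seq", "qual") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(is.na(x$id) | x$id == "" | grepl("^@|\\s", x$id))[1]
  if (!is.na(bad)) stop("invalid identifier in record ", bad, ": ", x$id[bad])
  bad <- which(!grepl("^[ACGTN]*$", x$seq))[1]
  if (!is.na(bad)) stop("record '", x$id[bad], "': sequence contains characters outside {A,C,G,T,N}")
  bad <- which(nchar(x$seq) != nchar(x$qual))[1]
  if (!is.na(bad)) {
    stop("record '", x$id[bad], "': sequence length ", nchar(x$seq[bad]),
         " != quality length ", nchar(x$qual[bad]))
  }
  ords <- utf8ToInt(paste(x$qual, collapse = ""))
  if (length(ords) && (min(ords) < 33L || max(ords) > 126L)) {
    stop("quality characters outside the printable Phred+33 range [33, 126]")
  }
  invisible(x)
}

#' Test whether a file is gzip-compressed
#'
#' @param path file path.
#' @return `TRUE` if the file starts with the gzip magic bytes `1f 8b`.
#' @export
is_gzip <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Read a FASTQ file
#'
#' Reads plain or gzip-compressed 4-line FASTQ (compression is detected from
#' the file content, not the extension). Quality strings are re-encoded to
#' Phred+33 when `qual_offset = 64`.
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @param qual_offset Phred encoding offset of the input, 33 (default) or 64.
#' @return A FASTQ record data frame (see [fastq_records()]).
#' @export
read_fastq <- function(path, qual_offset = 33L) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!qual_offset %in% c(33L, 64L)) stop("qual_offset must be 33 or 64")
  con <- file(path, "rt")  # transparently decompresses gzip
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) {
    return(fastq_records(character(), character(), character()))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ in ", path, ": ", length(lines),
         " lines is not a multiple of 4 (truncated record near '",
         lines[4L * (length(lines) %/% 4L) + 1L], "')")
  }
  idx <- seq(1L, length(lines), by = 4L)
  headers <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad <- which(!startsWith(headers, "@") | !startsWith(plus, "+"))[1]
  if (!is.na(bad)) {
    stop("malformed FASTQ in ", path, ": record ", bad,
         " ('", headers[bad], "') lacks the @/+ block structure")
  }
  headers <- substring(headers, 2L)
  bad <- which(nchar(seqs) != nchar(quals))[1]
  if (!is.na(bad)) {
    stop("malformed FASTQ in ", path, ": record '",
         sub("\\s.*$", "", headers[bad]), "' has sequence length ",
         nchar(seqs[bad]), " but quality length ", nchar(quals[bad]))
  }
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (qual_offset == 64L) {
    quals <- vapply(quals, shift_qual_64_to_33, character(1), USE.NAMES = FALSE)
  }
  out <- data.frame(id = id, desc = desc, seq = toupper(seqs), qual = quals,
                    stringsAsFactors = FALSE)
  validate_fastq_records(out)
  out
}

shift_qual_64_to_33 <- function(q) {
  if (!nzchar(q)) return(q)
  ords <- utf8ToInt(q) - 31L
  if (min(ords) < 33L) stop("quality below '@' under Phred+64 interpretation")
  intToUtf8(ords)
}

#' Write FASTQ records
#'
#' Writes standard 4-line FASTQ (no line wrapping) in input order.
#'
#' @param records FASTQ record data frame.
#' @param path output path.
#' @param gzip write gzip-compressed output; default: `TRUE` when `path`
#'   ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path, gzip = grepl("\\.gz$", path)) {
  validate_fastq_records(records)
  header <- ifelse(nzchar(records$desc), paste(records$id, records$desc), records$id)
  lines <- character(4L * nrow(records))
  if (nrow(records)) {
    idx <- 4L * (seq_len(nrow(records)) - 1L)
    lines[idx + 1L] <- paste0("@", header)
    lines[idx + 2L] <- records$seq
    lines[idx + 3L] <- "+"
    lines[idx + 4L] <- records$qual
  }
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Strip a mate suffix from a read identifier
#'
#' Removes a trailing `/1` or `/2` so that legacy mate identifiers compare
#' equal; Casava 1.8-style mate tokens live in the description and are
#' already excluded from `id`.
#'
#' @param id character vector of identifiers.
#' @return identifiers without mate suffixes.
#' @export
mate_base_id <- function(id) sub("/[12]$", "", id)

check_pairing <- function(fwd, rev) {
  if (nrow(fwd) != nrow(rev)) {
    stop("unpaired reads: ", nrow(fwd), " forward vs ", nrow(rev), " reverse")
  }
  bad <- which(mate_base_id(fwd$id) != mate_base_id(rev$id))[1]
  if (!is.na(bad)) {
    stop("mate identifiers disagree at pair ", bad, ": '", fwd$id[bad],
         "' vs '", rev$id[bad], "'")
  }
  invisible(TRUE)
}

#' Read paired FASTQ files
#'
#' @param path_fwd,path_rev forward and reverse FASTQ files.
#' @param qual_offset Phred encoding offset.
#' @return `list(forward = records, reverse = records)` with verified pairing.
#' @export
read_fastq_paired <- function(path_fwd, path_rev, qual_offset = 33L) {
  fwd <- read_fastq(path_fwd, qual_offset)
  rev <- read_fastq(path_rev, qual_offset)
  check_pairing(fwd, rev)
  list(forward = fwd, reverse = rev)
}

#' Read an interleaved FASTQ file
#'
#' Interleaved FASTQ is strict forward, reverse, forward, reverse order.
#' A trailing unpaired read is a fatal error.
#'
#' @param path interleaved FASTQ file.
#' @param qual_offset Phred encoding offset.
#' @return `list(forward = records, reverse = records)`.
#' @export
read_fastq_interleaved <- function(path, qual_offset = 33L) {
  x <- read_fastq(path, qual_offset)
  if (nrow(x) %% 2L != 0L) {
    stop("interleaved file ", path, " has an unpaired trailing read: ", x$id[nrow(x)])
  }
  odd <- seq_len(nrow(x)) %% 2L == 1L
  fwd <- x[odd, , drop = FALSE]
  rev <- x[!odd, , drop = FALSE]
  rownames(fwd) <- rownames(rev) <- NULL
  check_pairing(fwd, rev)
  list(forward = fwd, reverse = rev)
}

#' Interleave paired records
#'
#' @param pairs `list(forward = records, reverse = records)`.
#' @return A single record data frame in strict F,R,F,R order.
#' @export
interleave_pairs <- function(pairs) {
  check_pairing(pairs$forward, pairs$reverse)
  n <- nrow(pairs$forward)
  idx <- rep(seq_len(n), each = 2L)
  out <- rbind(pairs$forward, pairs$reverse)[rep(c(0L, n), n) + idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
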