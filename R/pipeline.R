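.profile_cache <- new.env(parent = emptyenv())

#' Default flank profile HMMs
#'
#' Builds (and memoizes) calibrated profiles for the three bundled
#' synthetic flank alignments.
#'
#' @param seed calibration seed.
#' @return named list of `profile_hmm` objects (`SSU_tail`, `R5.8S`,
#'   `LSU_head`).
#' @export
default_profiles <- function(seed = 101L) {
  key <- as.character(seed)
  if (!is.null(.profile_cache[[key]])) return(.profile_cache[[key]])
  alns <- default_flank_alignments()
  profs <- lapply(names(alns), function(nm) {
    build_profile(alns[[nm]], name = nm, seed = seed)
  })
  names(profs) <- names(alns)
  .profile_cache[[key]] <- profs
  profs
}

#' Run configuration for the trimming pipeline
#'
#' @param input input FASTQ (single-end or interleaved), or the forward
#'   file of a pair.
#' @param input2 reverse FASTQ for the two-file paired layout.
#' @param layout `"single"`, `"interleaved"` or `"paired2file"`.
#' @param region `"ITS1"`, `"ITS2"` or `"ALL"`.
#' @param outfile output FASTQ path (gzip if it ends in `.gz`).
#' @param logfile optional run log path.
#' @param cluster_id clustering identity in `[0.98, 1.00]` (default 0.995).
#' @param thresholds [heuristic_thresholds()].
#' @param merge [merge_params()].
#' @param profiles named list of calibrated profiles; default
#'   [default_profiles()] built with `seed`.
#' @param keep_excluded optional FASTQ path for excluded reads (untrimmed,
#'   with the exclusion reason tagged in the description).
#' @param outcome_tsv optional TSV path for per-read trim outcomes.
#' @param qual_offset Phred offset of the input (33 or 64).
#' @param reverse_complement_scan also scan each representative's reverse
#'   complement and keep the better-scoring orientation.
#' @param seed seed for profile calibration.
#' @param threads accepted for interface compatibility; this implementation
#'   is single-threaded.
#' @return validated configuration list.
#' @export
run_config <- function(input, input2 = NULL,
                       layout = c("single", "paired2file", "interleaved"),
                       region = c("ITS1", "ITS2", "ALL"),
                       outfile, logfile = NULL,
                       cluster_id = 0.995,
                       thresholds = heuristic_thresholds(),
                       merge = merge_params(),
                       profiles = NULL,
                       keep_excluded = NULL, outcome_tsv = NULL,
                       qual_offset = 33L,
                       reverse_complement_scan = FALSE,
                       seed = 101L, threads = 1L) {
  layout <- match.arg(layout)
  region <- match.arg(region)
  if (cluster_id < 0.98 || cluster_id > 1.00) {
    stop("cluster_id must be within [0.98, 1.00], got ", cluster_id)
  }
  if (layout == "paired2file" && is.null(input2)) {
    stop("layout 'paired2file' requires input2 (the reverse FASTQ)")
  }
  if (layout != "paired2file" && !is.null(input2)) {
    stop("input2 is only meaningful with layout 'paired2file'")
  }
  list(input = input, input2 = input2, layout = layout, region = region,
       outfile = outfile, logfile = logfile, cluster_id = cluster_id,
       thresholds = thresholds, merge = merge, profiles = profiles,
       keep_excluded = keep_excluded, outcome_tsv = outcome_tsv,
       qual_offset = as.integer(qual_offset),
       reverse_complement_scan = isTRUE(reverse_complement_scan),
       seed = as.integer(seed), threads = as.integer(threads))
}

region_profile_names <- function(region) unname(REGION_FLANKS[[region]])

scan_representative <- function(seq, profiles, region, thresholds, rc_scan) {
  hits <- scan_one_orientation(seq, profiles, region, thresholds)
  if (rc_scan) {
    rc_hits <- scan_one_orientation(revcomp(seq), profiles, region, thresholds)
    if (total_bits(rc_hits) > total_bits(hits)) {
      # map hit coordinates back to the forward strand
      L <- nchar(seq)
      if (!is.null(rc_hits)) {
        new_start <- L - rc_hits$seq_end
        rc_hits$seq_end <- L - rc_hits$seq_start
        rc_hits$seq_start <- new_start
        # flank roles swap sides on the reverse strand; keep names, the
        # caller sees coordinates in forward-read space
      }
      hits <- rc_hits
    }
  }
  hits
}

scan_one_orientation <- function(seq, profiles, region, thresholds) {
  out <- list()
  for (nm in region_profile_names(region)) {
    p <- profiles[[nm]]
    if (is.null(p)) stop("missing profile '", nm, "' for region ", region)
    if (!prefilter(p, seq, thresholds)) next
    h <- viterbi_local(p, seq, thresholds)
    if (!is.null(h)) out[[length(out) + 1L]] <- h
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

total_bits <- function(hits) if (is.null(hits)) -Inf else sum(hits$bit_score)

#' Run the full ITS trimming pipeline
#'
#' Reads FASTQ input, merges pairs (paired layouts), dereplicates and
#' greedily clusters the merged reads at `cluster_id` identity, locates the
#' region's flanks on each cluster representative with the profile HMMs,
#' propagates each representative's trim coordinates to all reads in its
#' cluster, and writes trimmed, quality-preserving FASTQ in the input read
#' order. The run log records counts at every stage and all parameters.
#'
#' @param config configuration from [run_config()].
#' @return Invisibly, `list(outcomes, counts, log)`.
#' @export
run_trim <- function(config) {
  cleanup <- c(config$outfile, config$keep_excluded, config$outcome_tsv)
  ok <- FALSE
  on.exit(if (!ok) unlink(cleanup))

  logln <- local({
    lines <- character()
    function(fmt = NULL, ...) {
      if (is.null(fmt)) return(lines)
      lines <<- c(lines, sprintf(fmt, ...))
      invisible(NULL)
    }
  })
  logln("itstrim run: layout=%s region=%s cluster_id=%g f1=%g f2=%g f3=%g",
        config$layout, config$region, config$cluster_id,
        config$thresholds$f1, config$thresholds$f2, config$thresholds$f3)
  logln("merge: min_overlap=%d max_mismatch_rate=%g quality_cap=%d; seed=%d; threads=%d (single-threaded implementation)",
        config$merge$min_overlap, config$merge$max_mismatch_rate,
        config$merge$quality_cap, config$seed, config$threads)

  profiles <- config$profiles
  if (is.null(profiles)) profiles <- default_profiles(config$seed)

  # 1. read
  if (config$layout == "single") {
    reads <- read_fastq(config$input, config$qual_offset)
    logln("input reads: %d (%s)", nrow(reads), config$input)
    merged <- reads
    unmerged_ids <- character()
  } else {
    pairs <- if (config$layout == "paired2file") {
      read_fastq_paired(config$input, config$input2, config$qual_offset)
    } else {
      read_fastq_interleaved(config$input, config$qual_offset)
    }
    logln("input pairs: %d", nrow(pairs$forward))
    mg <- merge_pairs(pairs, config$merge)
    merged <- mg$merged
    unmerged_ids <- mg$unmerged_ids
    logln("merged pairs: %d; unmerged (excluded): %d", nrow(merged),
          length(unmerged_ids))
  }
  if (anyDuplicated(merged$id)) stop("duplicate read identifiers in input")

  # 2. dereplicate + cluster
  uniques <- dereplicate_exact(merged)
  logln("unique sequences: %d", nrow(uniques))
  clustered <- cluster_greedy(uniques, config$cluster_id)
  reps <- attr(clustered, "representatives")
  logln("clusters at identity %g: %d", config$cluster_id, length(reps))

  # 3. boundary per representative, 4. propagate
  outcomes <- vector("list", length(reps))
  n_called <- 0L
  for (ci in seq_along(reps)) {
    rep_seq <- clustered$seq[reps[ci]]
    members <- which(clustered$cluster == ci)
    hits <- scan_representative(rep_seq, profiles, config$region,
                                config$thresholds,
                                config$reverse_complement_scan)
    call <- call_boundaries(hits, config$region, nchar(rep_seq),
                            seq_id = clustered$member_ids[[reps[ci]]][1])
    if (!is.null(call)) n_called <- n_called + 1L
    member_ids <- unlist(clustered$member_ids[members], use.names = FALSE)
    member_lens <- rep(nchar(clustered$seq[members]),
                       lengths(clustered$member_ids[members]))
    outcomes[[ci]] <- propagate_trim(member_ids, member_lens, call)
  }
  outcomes <- do.call(rbind, outcomes)
  if (length(unmerged_ids)) {
    outcomes <- rbind(outcomes,
                      data.frame(read_id = unmerged_ids,
                                 status = "excluded_unmerged",
                                 start = NA_integer_, stop = NA_integer_,
                                 stringsAsFactors = FALSE))
  }
  logln("representatives with a boundary call: %d / %d", n_called, length(reps))

  # 5. trim and write (input order; unmerged pairs have no merged record)
  res <- apply_trim(merged, outcomes)
  write_fastq(res$trimmed, config$outfile)
  logln("written: %d trimmed reads -> %s", nrow(res$trimmed), config$outfile)
  tab <- table(outcomes$status)
  for (nm in names(tab)) logln("  %s: %d", nm, tab[[nm]])
  stopifnot(nrow(merged) + length(unmerged_ids) == nrow(outcomes))

  if (!is.null(config$keep_excluded)) {
    write_fastq(res$excluded, config$keep_excluded)
    logln("excluded reads kept in %s", config$keep_excluded)
  }
  if (!is.null(config$outcome_tsv)) {
    write.table(outcomes, config$outcome_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(config$logfile)) writeLines(logln(), config$logfile)
  ok <- TRUE
  invisible(list(outcomes = outcomes,
                 counts = list(input = nrow(merged) + length(unmerged_ids),
                               merged = nrow(merged),
                               uniques = nrow(uniques),
                               clusters = length(reps),
                               called = n_called,
                               trimmed = nrow(res$trimmed),
                               by_status = as.list(tab)),
                 log = logln()))
}
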