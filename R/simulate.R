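#' Generate a synthetic conserved-flank multiple alignment
#'
#' Builds a small gapped alignment around a random ancestral sequence:
#' each member carries independent substitutions at `divergence`, and a few
#' mostly-gap columns are interleaved so the resulting profile has insert
#' states. The bundled flank alignments shipped with the package were made
#' with this generator (they are synthetic stand-ins, not database
#' sequences); users may supply real SSU/5.8S/LSU alignments instead.
#'
#' @param length number of match columns (ancestral sequence length).
#' @param n_seqs alignment depth.
#' @param divergence per-base substitution rate of each member vs the
#'   ancestor.
#' @param n_insert_cols number of mostly-gap (insert) columns to add.
#' @param seed RNG seed.
#' @return character vector of equal-length gapped sequences.
#' @export
make_flank_alignment <- function(length, n_seqs = 8L, divergence = 0.03,
                                 n_insert_cols = 2L, seed) {
  stopifnot(length >= 10L, n_seqs >= 2L)
  set.seed(seed)
  ancestor <- sample(BASES, length, replace = TRUE)
  rows <- lapply(seq_len(n_seqs), function(i) mutate_bases(ancestor, divergence))
  m <- do.call(rbind, rows)
  if (n_insert_cols > 0L) {
    at <- sort(sample(seq_len(length - 1L), n_insert_cols))
    n_occ <- max(1L, floor(n_seqs / 4L))  # < 50% occupancy => insert column
    for (k in rev(seq_along(at))) {
      col <- rep("-", n_seqs)
      col[sample(n_seqs, n_occ)] <- sample(BASES, n_occ, replace = TRUE)
      m <- cbind(m[, seq_len(at[k]), drop = FALSE], col,
                 m[, (at[k] + 1L):ncol(m), drop = FALSE])
    }
  }
  apply(m, 1, paste, collapse = "")
}

mutate_bases <- function(bases, rate) {
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b)
      sample(setdiff(BASES, b), 1L), character(1))
  }
  bases
}

#' Majority-rule consensus of an alignment's match columns
#'
#' @param alignment gapped alignment (any form accepted by
#'   [build_profile()]).
#' @return consensus DNA string over the match columns (columns with at
#'   most 50% gaps).
#' @export
flank_consensus <- function(alignment) {
  aln <- as_alignment_matrix(alignment)
  is_gap <- aln == "-" | aln == "."
  match_cols <- which(colMeans(is_gap) <= 0.5)
  cons <- vapply(match_cols, function(cc) {
    col <- aln[, cc]
    cnt <- table(factor(col[col %in% BASES], levels = BASES))
    BASES[which.max(cnt)]
  }, character(1))
  paste(cons, collapse = "")
}

#' Bundled synthetic flank alignments
#'
#' @return named list of gapped alignments for `SSU_tail`, `R5.8S`,
#'   `LSU_head`, read from the package's `extdata/flanks` directory.
#' @export
default_flank_alignments <- function() {
  dir <- system.file("extdata", "flanks", package = "itstrim")
  files <- c(SSU_tail = "ssu_tail_synthetic.afa",
             R5.8S = "r58s_synthetic.afa",
             LSU_head = "lsu_head_synthetic.afa")
  lapply(files, function(f) {
    as.character(Biostrings::readBStringSet(file.path(dir, f)))
  })
}

#' Simulation configuration
#'
#' Defines the amplicon structure the simulator emulates: each taxon's
#' insert is `SSU tail + ITS1 + 5.8S + ITS2 + LSU head`, with the conserved
#' flanks mutated per taxon at `substitution_rate_taxa` and the ITS regions
#' drawn uniformly at random (so taxa are unrelated in the spacers, as
#' hypervariable regions effectively are). Reads carry independent per-base
#' substitution errors and Phred qualities from a discretized truncated
#' normal; errors are drawn independently of the quality string (a
#' documented simplification).
#'
#' @param n_taxa number of taxa.
#' @param reads_per_taxon reads per taxon (scalar or length-`n_taxa`).
#' @param flank_alignments named list of gapped alignments (`SSU_tail`,
#'   `R5.8S`, `LSU_head`); default: the bundled synthetic set.
#' @param its1_length_range,its2_length_range inclusive length ranges of the
#'   spacer regions, in bases.
#' @param substitution_rate_taxa per-base substitution rate of each taxon's
#'   flanks relative to the flank consensus.
#' @param per_base_error_rate per-base sequencing substitution error rate.
#' @param quality_mean,quality_sd Phred quality model (truncated to
#'   `[2, 41]` and discretized).
#' @param read_length read length for paired mode; `NULL` emits one
#'   full-insert single-end read per fragment (pre-merged geometry).
#' @param paired emit forward/reverse pairs (reverse reads are
#'   reverse-complemented, as sequenced).
#' @param seed RNG seed (mandatory).
#' @return validated configuration list.
#' @export
sim_config <- function(n_taxa = 10L, reads_per_taxon = 50L,
                       flank_alignments = NULL,
                       its1_length_range = c(100L, 160L),
                       its2_length_range = c(100L, 160L),
                       substitution_rate_taxa = 0.05,
                       per_base_error_rate = 0.005,
                       quality_mean = 35, quality_sd = 3,
                       read_length = NULL, paired = FALSE, seed) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  if (is.null(flank_alignments)) flank_alignments <- default_flank_alignments()
  stopifnot(all(c("SSU_tail", "R5.8S", "LSU_head") %in% names(flank_alignments)),
            n_taxa >= 1L, all(reads_per_taxon >= 1L),
            length(reads_per_taxon) %in% c(1L, n_taxa),
            length(its1_length_range) == 2L, its1_length_range[1] <= its1_length_range[2],
            length(its2_length_range) == 2L, its2_length_range[1] <= its2_length_range[2],
            substitution_rate_taxa >= 0, substitution_rate_taxa < 1,
            per_base_error_rate >= 0, per_base_error_rate < 1,
            quality_sd >= 0)
  cfg <- list(n_taxa = as.integer(n_taxa),
              reads_per_taxon = rep_len(as.integer(reads_per_taxon), n_taxa),
              flank_alignments = flank_alignments,
              its1_length_range = as.integer(its1_length_range),
              its2_length_range = as.integer(its2_length_range),
              substitution_rate_taxa = substitution_rate_taxa,
              per_base_error_rate = per_base_error_rate,
              quality_mean = quality_mean, quality_sd = quality_sd,
              read_length = if (is.null(read_length)) NULL else as.integer(read_length),
              paired = isTRUE(paired), seed = as.integer(seed))
  cfg$flank_consensus <- lapply(flank_alignments, flank_consensus)
  if (cfg$paired) {
    if (is.null(cfg$read_length)) stop("paired mode requires read_length")
    max_insert <- nchar(cfg$flank_consensus$SSU_tail) +
      its1_length_range[2] + nchar(cfg$flank_consensus$R5.8S) +
      its2_length_range[2] + nchar(cfg$flank_consensus$LSU_head)
    if (2L * cfg$read_length - 12L < max_insert) {
      stop("read_length ", cfg$read_length, " too short: pairs from inserts up to ",
           max_insert, " bases could not overlap by the minimum 12 bases")
    }
  }
  cfg
}

#' Simulate ITS amplicon reads with ground-truth boundaries
#'
#' @param config configuration from [sim_config()].
#' @param out_dir optional directory; when given, reads
#'   (`reads.fastq.gz` or `reads_R1/R2.fastq.gz`), the truth table
#'   (`truth.tsv`) and the flank alignments used (`*.afa`) are written
#'   there.
#' @return `list(reads, pairs, truth, taxa, config)`: `reads` is the
#'   single-end record table (`NULL` in paired mode), `pairs` the
#'   forward/reverse record tables (`NULL` in single mode), `truth` one row
#'   per read (`read_id`, `taxon`, `its1_start`, `its1_stop`, `its2_start`,
#'   `its2_stop`, 0-based half-open on the true insert) and `taxa` one row
#'   per taxon with the noiseless insert.
#' @export
simulate_amplicons <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  cons <- config$flank_consensus

  taxa <- vector("list", config$n_taxa)
  for (t in seq_len(config$n_taxa)) {
    ssu <- mutate_string(cons$SSU_tail, config$substitution_rate_taxa)
    r58 <- mutate_string(cons$R5.8S, config$substitution_rate_taxa)
    lsu <- mutate_string(cons$LSU_head, config$substitution_rate_taxa)
    its1 <- random_dna(sample_range(config$its1_length_range))
    its2 <- random_dna(sample_range(config$its2_length_range))
    insert <- paste0(ssu, its1, r58, its2, lsu)
    b <- cumsum(nchar(c(ssu, its1, r58, its2, lsu)))
    taxa[[t]] <- data.frame(taxon = t, insert = insert,
                            its1_start = b[1], its1_stop = b[2],
                            its2_start = b[3], its2_stop = b[4],
                            stringsAsFactors = FALSE)
  }
  taxa <- do.call(rbind, taxa)

  tx <- rep(seq_len(config$n_taxa), config$reads_per_taxon)
  n_reads <- length(tx)
  read_id <- sprintf("taxon%03d_read%05d", tx, seq_len(n_reads))
  truth <- data.frame(read_id = read_id, taxon = tx,
                      its1_start = taxa$its1_start[tx],
                      its1_stop = taxa$its1_stop[tx],
                      its2_start = taxa$its2_start[tx],
                      its2_stop = taxa$its2_stop[tx],
                      stringsAsFactors = FALSE)

  inserts <- taxa$insert[tx]
  reads <- NULL; pairs <- NULL
  if (!config$paired) {
    seqs <- vapply(inserts, function(s) {
      if (is.null(config$read_length)) s else substr(s, 1L, config$read_length)
    }, character(1), USE.NAMES = FALSE)
    seqs <- add_read_errors(seqs, config$per_base_error_rate)
    quals <- draw_quals(nchar(seqs), config$quality_mean, config$quality_sd)
    reads <- fastq_records(read_id, seqs, quals)
  } else {
    L <- config$read_length
    ilen <- nchar(inserts)
    rl <- pmin.int(L, ilen)
    fseq <- substr(inserts, 1L, rl)
    rseq <- revcomp(substr(inserts, ilen - rl + 1L, ilen))
    fseq <- add_read_errors(fseq, config$per_base_error_rate)
    rseq <- add_read_errors(rseq, config$per_base_error_rate)
    fq <- draw_quals(nchar(fseq), config$quality_mean, config$quality_sd)
    rq <- draw_quals(nchar(rseq), config$quality_mean, config$quality_sd)
    pairs <- list(forward = fastq_records(read_id, fseq, fq),
                  reverse = fastq_records(read_id, rseq, rq))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!config$paired) {
      write_fastq(reads, file.path(out_dir, "reads.fastq.gz"))
    } else {
      write_fastq(pairs$forward, file.path(out_dir, "reads_R1.fastq.gz"))
      write_fastq(pairs$reverse, file.path(out_dir, "reads_R2.fastq.gz"))
    }
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (nm in names(config$flank_alignments)) {
      aln <- config$flank_alignments[[nm]]
      writeLines(as.vector(rbind(paste0(">", nm, "_", seq_along(aln)), aln)),
                 file.path(out_dir, paste0(gsub("[^A-Za-z0-9]", "", nm), ".afa")))
    }
  }

  list(reads = reads, pairs = pairs, truth = truth, taxa = taxa,
       config = config)
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

mutate_string <- function(s, rate) {
  paste(mutate_bases(strsplit(s, "")[[1]], rate), collapse = "")
}

add_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) mutate_string(s, rate), character(1),
         USE.NAMES = FALSE)
}

draw_quals <- function(lens, mean, sd) {
  vapply(lens, function(n) {
    q <- as.integer(round(rnorm(n, mean, sd)))
    q <- pmin.int(pmax.int(q, 2L), 41L)
    intToUtf8(q + 33L)
  }, character(1))
}
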