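test_that("global alignment: identity, single-gap example, empty input", {
  set.seed(901)
  a <- random_dna_str(25)
  g <- global_align(a, a)
  expect_equal(g$score, 2 * 25)
  expect_equal(g$a_aln, a)

  # ACGT vs ACT: 3 matches and one single-base gap = 2+2-0.5+2
  g <- global_align("ACGT", "ACT")
  expect_equal(g$score, 5.5)
  expect_equal(nchar(g$a_aln), 4L)
  expect_equal(g$b_aln, "AC-T")

  expect_error(global_align("", "ACGT"), "empty")
})

test_that("alignment score equals the brute-force recursion oracle", {
  set.seed(902)
  sch <- scoring_scheme()
  for (i in 1:200) {
    a <- random_dna_str(sample(1:10, 1))
    b <- random_dna_str(sample(1:10, 1))
    expect_equal(global_align(a, b, sch)$score, oracle_align_score(a, b, sch),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("alignment score agrees with an independent aligner on longer pairs", {
  # Biostrings charges open+extend for every gap base; open - extend maps our
  # first-base-open convention onto it
  set.seed(903)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:40) {
    a <- random_dna_str(sample(30:120, 1))
    bv <- strsplit(a, "")[[1]]
    for (p in sample(length(bv), sample(0:6, 1))) {
      bv[p] <- sample(setdiff(DNA4, bv[p]), 1)
    }
    if (runif(1) < 0.5) bv <- bv[-sample(length(bv), sample(1:3, 1))]
    b <- paste(bv, collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0.4, gapExtension = 0.1)
    expect_equal(global_align(a, b)$score, Biostrings::score(ref),
                 tolerance = 1e-6)
  }
})

test_that("trim offsets follow the coordinate-difference definition", {
  src <- paste(rep(strsplit("ACGTTGCAAT", "")[[1]], 30), collapse = "")
  set.seed(904)
  src <- random_dna_str(250)
  a <- substr(src, 11, 200)   # trimmed at (10, 200)
  b <- substr(src, 13, 200)   # trimmed at (12, 200)
  g <- global_align(a, b)
  off <- alignment_offsets(g$a_aln, g$b_aln)
  expect_equal(unname(off), c(2L, 0L))

  cmp <- compare_trim_sets(fastq_records("r", a, strrep("I", nchar(a))),
                           fastq_records("r", b, strrep("I", nchar(b))))
  expect_equal(cmp$comparisons$start_offset, 2L)
  expect_equal(cmp$comparisons$stop_offset, 0L)
  expect_equal(cmp$summary$fraction_within, 1)   # within the 2-base window
  expect_equal(unname(cmp$summary$fraction_by_window["0"]), 0)
})

test_that("set comparison: identical sets, symmetry, windows, id handling", {
  recs <- random_records_fixture(30, seed = 905, len_range = c(60, 120))
  cmp <- compare_trim_sets(recs, recs)
  expect_equal(cmp$summary$fraction_within, 1)
  expect_equal(cmp$summary$n_identical, 30L)
  expect_true(all(cmp$comparisons$identical))

  # exact offset recovery on overhangs with a unique optimal alignment:
  # N never matches anything, so N overhangs must sit in terminal gaps
  set.seed(906)
  for (i in 1:10) {
    core <- random_dna_str(80)
    d <- sample(1:4, 1); e <- sample(0:4, 1)
    long <- paste0(strrep("N", d), core, strrep("N", e))
    ra <- fastq_records("x", core, strrep("I", nchar(core)))
    rb <- fastq_records("x", long, strrep("I", nchar(long)))
    cmp <- compare_trim_sets(ra, rb)
    expect_equal(cmp$comparisons$start_offset, -d)
    expect_equal(cmp$comparisons$stop_offset, e)
  }

  # symmetry and window monotonicity on random trimmings of a shared source
  src <- vapply(1:20, function(i) random_dna_str(200), character(1))
  starts <- 6L + sample(-3:3, 20, replace = TRUE)
  stops <- 180L + sample(-3:3, 20, replace = TRUE)
  a <- fastq_records(sprintf("r%02d", 1:20),
                     substr(src, 6, 180), strrep("I", 175))
  b <- fastq_records(sprintf("r%02d", 1:20),
                     substr(src, starts, stops),
                     vapply(stops - starts + 1L, function(n) strrep("I", n),
                            character(1)))
  ab <- compare_trim_sets(a, b)
  ba <- compare_trim_sets(b, a)
  expect_equal(ab$comparisons$start_offset, -ba$comparisons$start_offset)
  expect_equal(ab$comparisons$stop_offset, -ba$comparisons$stop_offset)
  expect_equal(ab$summary$fraction_within, ba$summary$fraction_within)
  # offsets agree with the trim-coordinate differences up to tie alignments
  expect_true(all(abs(ab$comparisons$start_offset - (starts - 6L)) <= 4))
  expect_true(all(abs(ab$comparisons$stop_offset - (stops - 180L)) <= 4))
  expect_gte(mean(ab$comparisons$start_offset == starts - 6L), 0.8)
  # the window summary is monotonically non-decreasing in window size
  expect_true(all(diff(ab$summary$fraction_by_window) >= 0))

  # reads present in only one set are reported separately
  cmp <- compare_trim_sets(a, b[-c(1, 2), ])
  expect_equal(cmp$summary$n_only_a, 2L)
  expect_equal(cmp$summary$n_common, 18L)

  dup <- rbind(a, a[1, ])
  expect_error(compare_trim_sets(dup, b), "duplicate")
})

test_that("comparison report writes the summary and per-read table", {
  recs <- random_records_fixture(10, seed = 907)
  cmp <- compare_trim_sets(recs, recs)
  f <- withr::local_tempfile(fileext = ".txt")
  write_comparison_report(cmp, f)
  txt <- readLines(f)
  expect_true(any(grepl("reads compared:\\s+10", txt)))
  tab <- read.table(paste0(f, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 10L)
})
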