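mk_pair <- function(fseq, rseq, fq = NULL, rq = NULL) {
  if (is.null(fq)) fq <- strrep("I", nchar(fseq))
  if (is.null(rq)) rq <- strrep("I", nchar(rseq))
  list(forward = fastq_records("p1", fseq, fq),
       reverse = fastq_records("p1", rseq, rq))
}

test_that("overlap detection: full, partial, and absent overlaps", {
  set.seed(401)
  ins <- random_dna_str(20)
  p <- mk_pair(ins, revcomp(ins))
  expect_equal(find_overlap(p$forward, p$reverse), 20L)

  # 15-base overlap: forward covers insert[1..25], reverse covers [11..35]
  ins <- random_dna_str(35)
  p <- mk_pair(substr(ins, 1, 25), revcomp(substr(ins, 11, 35)))
  expect_equal(find_overlap(p$forward, p$reverse), 15L)

  # unrelated 50-mers at mismatch rate 0: no overlap
  params <- merge_params(min_overlap = 12L, max_mismatch_rate = 0)
  p <- mk_pair(random_dna_str(50), random_dna_str(50))
  expect_null(find_overlap(p$forward, p$reverse, params))
})

test_that("overlap choice matches the brute-force scan oracle", {
  set.seed(402)
  params <- merge_params()
  for (i in 1:60) {
    ins <- random_dna_str(sample(40:90, 1))
    L <- sample(25:60, 1)
    rl <- min(L, nchar(ins))
    fseq <- substr(ins, 1, rl)
    rseq <- revcomp(substr(ins, nchar(ins) - rl + 1, nchar(ins)))
    # sprinkle errors
    fseq <- chartr("A", sample(c("A", "C"), 1), fseq)
    got <- find_overlap(fastq_records("x", fseq, strrep("I", nchar(fseq))),
                        fastq_records("x", rseq, strrep("I", nchar(rseq))))
    want <- oracle_find_overlap(fseq, rseq, params$min_overlap,
                                params$max_mismatch_rate)
    expect_identical(got, want)
  }
})

test_that("consensus quality rules: capped sum, winner-takes, ties, N", {
  # q30 = '?', full 12-base overlap
  ins <- "ACGTACGTACGT"
  p <- mk_pair(ins, revcomp(ins), strrep("?", 12), strrep("?", 12))
  m <- merge_pair(p$forward, p$reverse)
  expect_equal(m$seq, ins)
  expect_equal(m$qual, strrep("J", 12))  # min(30+30, 41) = 41 -> 'J'
  expect_equal(m$overlap_length, 12L)

  # disagreement: forward q35 ('D') vs reverse q20 ('5') -> forward base, q15 ('0')
  alt <- paste0("T", substr(ins, 2, 12))
  p <- mk_pair(ins, revcomp(alt), strrep("D", 12), strrep("5", 12))
  m <- merge_pair(p$forward, p$reverse)
  expect_equal(substr(m$seq, 1, 1), "A")
  expect_equal(utf8ToInt(substr(m$qual, 1, 1)) - 33L, 35L - 20L)

  # quality tie -> forward base with quality 2
  p <- mk_pair(ins, revcomp(alt), strrep("D", 12), strrep("D", 12))
  m <- merge_pair(p$forward, p$reverse)
  expect_equal(substr(m$seq, 1, 1), "A")
  expect_equal(utf8ToInt(substr(m$qual, 1, 1)) - 33L, 2L)

  # N never wins a disagreement regardless of quality
  nf <- paste0("N", substr(ins, 2, 12))
  p <- mk_pair(nf, revcomp(ins), strrep("I", 12), strrep("#", 12))
  m <- merge_pair(p$forward, p$reverse)
  expect_equal(substr(m$seq, 1, 1), "A")
})

test_that("read-through pairs are clipped to the insert", {
  set.seed(403)
  ins <- random_dna_str(30)
  junk1 <- strrep("A", 10); junk2 <- strrep("C", 10)
  fseq <- paste0(ins, junk1)               # reads past the 30 bp insert
  rseq <- revcomp(paste0(junk2, ins))
  m <- merge_pair(fastq_records("x", fseq, strrep("I", 40)),
                  fastq_records("x", rseq, strrep("I", 40)))
  expect_equal(m$seq, ins)
  expect_equal(nchar(m$qual), 30L)
})

test_that("merged length law and error-free reconstruction on simulated pairs", {
  cfg <- sim_config(n_taxa = 6, reads_per_taxon = 5, per_base_error_rate = 0.005,
                    paired = TRUE, read_length = 300L, seed = 404)
  sim <- simulate_amplicons(cfg)
  mg <- merge_pairs(sim$pairs)
  expect_equal(nrow(mg$merged) + length(mg$unmerged_ids), mg$n_input)
  lf <- nchar(sim$pairs$forward$seq[match(mg$merged$id, sim$pairs$forward$id)])
  lr <- nchar(sim$pairs$reverse$seq[match(mg$merged$id, sim$pairs$reverse$id)])
  expect_equal(nchar(mg$merged$seq), lf + lr - mg$merged$overlap_length)

  cfg0 <- sim_config(n_taxa = 6, reads_per_taxon = 3, per_base_error_rate = 0,
                     paired = TRUE, read_length = 300L, seed = 405)
  s0 <- simulate_amplicons(cfg0)
  m0 <- merge_pairs(s0$pairs)
  expect_equal(length(m0$unmerged_ids), 0L)
  tx <- s0$truth$taxon[match(m0$merged$id, s0$truth$read_id)]
  expect_equal(m0$merged$seq, s0$taxa$insert[tx])
  # quality strings co-trimmed with sequences throughout
  expect_equal(nchar(m0$merged$qual), nchar(m0$merged$seq))
})
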