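test_that("profile construction: emission counting with and without pseudocounts", {
  # single-column alignment of all 'A', no pseudocount
  p <- build_profile(c("A", "A"), name = "one", pseudocount = 0,
                     calib_n = 100L, calib_len = 20L, seed = 601)
  expect_equal(p$M, 1L)
  expect_equal(unname(p$match_emissions[1, ]), c(1, 0, 0, 0))

  # add-one arithmetic: 2 'A' observations, pseudocount 1 -> 3/6 vs 1/6
  p <- build_profile(c("A", "A"), name = "one", pseudocount = 1,
                     calib_n = 100L, calib_len = 20L, seed = 601)
  expect_equal(unname(p$match_emissions[1, ]), c(3, 1, 1, 1) / 6)

  # mostly-gap columns become insert states
  p <- toy_profile("gapped4")
  expect_equal(p$M, 4L)

  expect_error(build_profile(character(), name = "x"), "empty|at least")
  # emission rows and transition groups are proper distributions
  p <- test_profiles()$SSU_tail
  expect_true(all(abs(rowSums(p$match_emissions) - 1) < 1e-9))
  expect_true(all(abs(rowSums(p$transitions[, c("MM", "MI", "MD")]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(p$transitions[, c("IM", "II")]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(p$transitions[, c("DM", "DD")]) - 1) < 1e-9))
})

test_that("Gumbel calibration is self-consistent on fresh background sequences", {
  p <- test_profiles()$SSU_tail
  set.seed(602)
  scores <- vapply(1:1000, function(i) {
    r <- paste(sample(DNA4, p$calibration$len, replace = TRUE,
                      prob = p$background), collapse = "")
    viterbi_local(p, r, thresholds = NULL)$bit_score
  }, numeric(1))
  top_e <- score_significance(p, max(scores))$e_value
  # the best of 1000 random sequences should have E-value near 1
  expect_gt(top_e, 0.02)
  expect_lt(top_e, 20)
})

test_that("local Viterbi: consensus self-hit spans the profile with positive bits", {
  for (p in test_profiles()) {
    h <- viterbi_local(p, p$consensus)
    expect_false(is.null(h))
    expect_gt(h$bit_score, 0)
    expect_equal(h$seq_start, 0L)
    expect_equal(h$seq_end, nchar(p$consensus))
    expect_equal(h$profile_start, 0L)
    expect_equal(h$profile_end, p$M)
  }
})

test_that("Viterbi score equals exhaustive path enumeration on toy profiles", {
  p3 <- toy_profile("uniform3")
  p4 <- toy_profile("gapped4")
  # all reads of length 1..3 over ACGT for M=3; sampled longer reads for both
  reads <- unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(DNA4), L)), 1, paste, collapse = "")
  }))
  for (r in reads) {
    v <- viterbi_local(p3, r, thresholds = NULL)
    expect_equal(v$bit_score, oracle_viterbi_score(p3, r), tolerance = 1e-9,
                 info = r)
  }
  set.seed(603)
  for (i in 1:40) {
    r <- random_dna_str(sample(4:6, 1))
    for (p in list(p3, p4)) {
      v <- viterbi_local(p, r, thresholds = NULL)
      expect_equal(v$bit_score, oracle_viterbi_score(p, r), tolerance = 1e-9,
                   info = paste(p$name, r))
    }
  }
})

test_that("random background reads are rejected at f3 = 1e-6; lowering f3 never adds hits", {
  p <- test_profiles()$R5.8S
  set.seed(604)
  reads <- vapply(1:50, function(i) random_dna_str(200), character(1))
  hits6 <- lapply(reads, function(r) viterbi_local(p, r))
  expect_true(all(vapply(hits6, is.null, logical(1))))
  # monotonicity on reads that do hit: a stricter f3 yields a subset
  cfg <- sim_config(n_taxa = 3, reads_per_taxon = 2, per_base_error_rate = 0.01,
                    seed = 605)
  sim <- simulate_amplicons(cfg)
  for (r in sim$reads$seq) {
    lo <- viterbi_local(p, r, heuristic_thresholds(f3 = 1e-12))
    hi <- viterbi_local(p, r, heuristic_thresholds(f3 = 1e-6))
    if (!is.null(lo)) expect_false(is.null(hi))
  }
})

test_that("prefilter: consensus passes, degenerate threshold passes everything, conservative", {
  p <- test_profiles()$SSU_tail
  expect_true(prefilter(p, p$consensus))
  set.seed(606)
  r <- random_dna_str(120)
  expect_true(prefilter(p, r, heuristic_thresholds(f1 = 1)))
  # conservativeness: a read the prefilter rejects has no passing Viterbi hit
  for (i in 1:200) {
    r <- random_dna_str(150)
    if (!prefilter(p, r)) {
      expect_null(viterbi_local(p, r))
    }
  }
})

test_that("boundary calls follow the flank geometry and fallback rules", {
  hit <- function(profile, s, e, bits = 50) {
    data.frame(profile = profile, seq_id = "r", seq_start = s, seq_end = e,
               profile_start = 0L, profile_end = 10L, ali_from = s, ali_to = e,
               bit_score = bits, e_value = 1e-20, stringsAsFactors = FALSE)
  }
  hits <- rbind(hit("SSU_tail", 0, 42), hit("R5.8S", 260, 300))
  b <- call_boundaries(hits, "ITS1", read_length = 400)
  expect_equal(c(b$start, b$stop), c(42L, 260L))
  expect_true(b$left_flank_found && b$right_flank_found)

  # no hits at all -> excluded
  expect_null(call_boundaries(NULL, "ITS1", 400))
  expect_null(call_boundaries(hits[0, ], "ITS2", 400))

  # one flank missing -> edge fallback with the flag down
  b <- call_boundaries(hit("R5.8S", 260, 300), "ITS1", 400)
  expect_equal(c(b$start, b$stop), c(0L, 260L))
  expect_false(b$left_flank_found)
  b <- call_boundaries(hit("SSU_tail", 0, 42), "ITS1", 400)
  expect_equal(c(b$start, b$stop), c(42L, 400L))
  expect_false(b$right_flank_found)

  # empty interval -> excluded
  expect_null(call_boundaries(rbind(hit("SSU_tail", 0, 300), hit("R5.8S", 260, 320)),
                              "ITS1", 400))

  # best hit per profile: higher bit score wins, ties leftmost
  hits <- rbind(hit("SSU_tail", 0, 42, bits = 10), hit("SSU_tail", 5, 50, bits = 60),
                hit("R5.8S", 260, 300))
  expect_equal(call_boundaries(hits, "ITS1", 400)$start, 50L)
  hits <- rbind(hit("SSU_tail", 10, 42, bits = 50), hit("SSU_tail", 5, 50, bits = 50),
                hit("R5.8S", 260, 300))
  expect_equal(call_boundaries(hits, "ITS1", 400)$start, 50L)
})

test_that("domtblout parsing: coordinate shift, comments, malformed lines, round trip", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c(
    "# comment only",
    paste("rep1 - 600 my58S - 140 1e-40 120.5 0.0 1 1 1e-40 1e-40 120.5 0.0",
          "1 140 43 260 43 260 0.98 -")), f)
  hits <- parse_domtblout(f, profile_map = c(my58S = "R5.8S"))
  expect_equal(hits$profile, "R5.8S")
  expect_equal(hits$seq_start, 42L)   # env from 43 -> 0-based 42
  expect_equal(hits$seq_end, 260L)    # env to 260 -> half-open 260

  writeLines("# nothing here", f)
  expect_equal(nrow(parse_domtblout(f)), 0L)

  writeLines("rep1 broken line", f)
  expect_error(parse_domtblout(f), "line 1")

  set.seed(607)
  hits <- data.frame(
    profile = c("SSU_tail", "R5.8S", "LSU_head"), seq_id = c("a", "b", "c"),
    seq_start = c(0L, 100L, 400L), seq_end = c(60L, 240L, 460L),
    profile_start = c(0L, 0L, 2L), profile_end = c(60L, 140L, 58L),
    bit_score = c(61.25, 150.5, 48.875), e_value = c(1e-20, 2.5e-60, 4e-15),
    stringsAsFactors = FALSE)
  write_domtblout(hits, f)
  back <- parse_domtblout(f)
  expect_equal(back[names(hits)], hits)
})
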