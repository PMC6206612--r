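test_that("exact dereplication counts, sorts and conserves reads", {
  seqs <- c(rep("TTTT", 3), rep("ACGT", 10), "GGGG")
  ids <- sprintf("r%02d", seq_along(seqs))
  d <- dereplicate_exact(seqs, ids)
  expect_equal(d$seq, c("ACGT", "TTTT", "GGGG"))
  expect_equal(d$abundance, c(10L, 3L, 1L))
  expect_equal(d$abundance, lengths(d$member_ids))
  expect_setequal(unlist(d$member_ids), ids)

  # all distinct: n entries, abundance 1, lexicographic tie-break
  set.seed(501)
  s <- unique(vapply(1:40, function(i) random_dna_str(12), character(1)))
  d <- dereplicate_exact(s)
  expect_equal(nrow(d), length(s))
  expect_true(all(d$abundance == 1L))
  expect_equal(d$seq, sort(s))
  expect_equal(sum(d$abundance), length(s))
})

test_that("pairwise identity: trivial cases and the 3-in-600 clustering example", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_error(pairwise_identity("", "ACGT"), "empty")

  # 600 bp differing by 3 substitutions: identity 597/600 = 0.995, so the
  # pair stays together at the default 99.5% clustering identity
  set.seed(502)
  a <- random_dna_str(600)
  bv <- strsplit(a, "")[[1]]
  for (p in sample(600, 3)) bv[p] <- setdiff(DNA4, bv[p])[1]
  b <- paste(bv, collapse = "")
  expect_equal(pairwise_identity(a, b), 597 / 600)
  cl <- cluster_greedy(dereplicate_exact(c(a, b)), threshold = 0.995)
  expect_equal(max(cl$cluster), 1L)
})

test_that("identity equals the exhaustive alignment-enumeration oracle", {
  set.seed(503)
  sch <- identity_scheme()
  for (i in 1:15) {
    a <- random_dna_str(sample(3:7, 1))
    b <- random_dna_str(sample(3:7, 1))
    ids <- oracle_identity_set(a, b, sch)
    expect_true(any(abs(pairwise_identity(a, b, sch) - ids) < 1e-9),
                info = paste(a, b))
  }
})

test_that("greedy clustering: degenerate threshold, first-fit rule, validation", {
  set.seed(504)
  s <- vapply(1:30, function(i) random_dna_str(40), character(1))
  d <- dereplicate_exact(s)
  cl <- cluster_greedy(d, threshold = 1.00)
  expect_equal(max(cl$cluster), nrow(d))   # one cluster per distinct sequence

  # A, A-with-1-substitution (len 400, identity 399/400 >= 0.995), unrelated B
  a <- random_dna_str(400)
  a2v <- strsplit(a, "")[[1]]; a2v[200] <- setdiff(DNA4, a2v[200])[1]
  seqs <- c(rep(a, 5), rep(paste(a2v, collapse = ""), 2), rep(random_dna_str(400), 3))
  # abundance order: A (5), B (3), A-variant (2); the variant joins A's cluster
  cl <- cluster_greedy(dereplicate_exact(seqs), threshold = 0.995)
  expect_equal(max(cl$cluster), 2L)
  expect_equal(cl$cluster, c(1L, 2L, 1L))

  expect_error(cluster_greedy(d, threshold = 0.9), "0.98")
  expect_error(cluster_greedy(d, threshold = 1.01), "0.98")

  # representatives were founded in scan (descending-abundance) order
  reps <- attr(cl, "representatives")
  expect_true(all(diff(reps) > 0))
  m <- cluster_map(cl)
  expect_equal(nrow(m), length(seqs))
  expect_equal(anyDuplicated(m$read_id), 0L)
})

test_that("clustering coarsens as the threshold drops and k-mer screen is lossless", {
  cfg <- sim_config(n_taxa = 8, reads_per_taxon = 10, per_base_error_rate = 0.01,
                    seed = 505)
  d <- dereplicate_exact(simulate_amplicons(cfg)$reads)
  thresholds <- c(1.00, 0.995, 0.98)
  n_clusters <- integer(0)
  prev <- NULL
  for (t in thresholds) {
    cl <- cluster_greedy(d, threshold = t)
    n_clusters <- c(n_clusters, max(cl$cluster))
    if (!is.null(prev)) {
      # coarsening: reads together at the higher threshold stay together
      agree <- tapply(cl$cluster, prev, function(v) length(unique(v)))
      expect_true(all(agree == 1L))
    }
    prev <- cl$cluster
    # screen must not change the result
    cl_noscreen <- cluster_greedy(d, threshold = t, use_prefilter = FALSE)
    expect_identical(cl$cluster, cl_noscreen$cluster)
  }
  expect_true(all(diff(n_clusters) <= 0))
})
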