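# Independent oracles used across the suite. These deliberately re-derive
# results by enumeration/recursion rather than calling the package's DP code.

DNA4 <- c("A", "C", "G", "T")

random_dna_str <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

random_records_fixture <- function(n, seed, len_range = c(20L, 80L)) {
  set.seed(seed)
  vals <- len_range[1]:len_range[2]
  lens <- vals[sample.int(length(vals), n, replace = TRUE)]
  seqs <- vapply(lens, random_dna_str, character(1))
  quals <- vapply(lens, function(l) {
    intToUtf8(sample(33:74, l, replace = TRUE))
  }, character(1))
  fastq_records(sprintf("read%04d", seq_len(n)), seqs, quals,
                desc = ifelse(seq_len(n) %% 2 == 0, "1:N:0:ACGT", ""))
}

# brute-force affine global alignment score (memoized recursion on suffixes;
# first gap base costs `open`, subsequent bases `extend`)
oracle_align_score <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j] && av[i] != "N") scheme$match else scheme$mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0L))
    }
    if (j <= m) {
      cost <- if (state == 1L) scheme$gap_extend else scheme$gap_open
      best <- max(best, cost + rec(i, j + 1, 1L))
    }
    if (i <= n) {
      cost <- if (state == 2L) scheme$gap_extend else scheme$gap_open
      best <- max(best, cost + rec(i + 1, j, 2L))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

# enumerate every global alignment of two short strings; return the set of
# identities achieved by the optimal-score alignments
oracle_identity_set <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  out <- list()
  rec <- function(i, j, state, score, matches, cols) {
    if (i > n && j > m) {
      out[[length(out) + 1L]] <<- c(score = score, id = matches / cols)
      return(invisible())
    }
    if (i <= n && j <= m) {
      is_match <- av[i] == bv[j] && av[i] != "N"
      s <- if (is_match) scheme$match else scheme$mismatch
      rec(i + 1, j + 1, 0L, score + s, matches + is_match, cols + 1)
    }
    if (j <= m) {
      cost <- if (state == 1L) scheme$gap_extend else scheme$gap_open
      rec(i, j + 1, 1L, score + cost, matches, cols + 1)
    }
    if (i <= n) {
      cost <- if (state == 2L) scheme$gap_extend else scheme$gap_open
      rec(i + 1, j, 2L, score + cost, matches, cols + 1)
    }
  }
  rec(1L, 1L, 0L, 0, 0, 0)
  tab <- do.call(rbind, out)
  best <- max(tab[, "score"])
  unique(tab[abs(tab[, "score"] - best) < 1e-9, "id"])
}

# exhaustive enumeration of all local profile-HMM state paths (entry at any
# match state with cost log2(1/M), exit after any match state); returns the
# best bit score
oracle_viterbi_score <- function(profile, read) {
  M <- profile$M
  x <- match(strsplit(read, "")[[1]], DNA4)
  L <- length(x)
  em <- profile$lodds$em; ins <- profile$lodds$ins; tr <- profile$lodds$tr
  best <- -Inf
  rec <- function(type, j, i, sc) {
    # in state (type, j) having consumed x[1..i] of the local window
    if (type == "M") best <<- max(best, sc)
    if (j >= M) return(invisible())
    if (type == "M") {
      if (i < L) rec("M", j + 1, i + 1, sc + tr[j, "MM"] + em[j + 1, x[i + 1]])
      if (i < L && j <= M - 1) rec("I", j, i + 1, sc + tr[j, "MI"] + ins[x[i + 1]])
      rec("D", j + 1, i, sc + tr[j, "MD"])
    } else if (type == "I") {
      if (i < L) rec("M", j + 1, i + 1, sc + tr[j, "IM"] + em[j + 1, x[i + 1]])
      if (i < L) rec("I", j, i + 1, sc + tr[j, "II"] + ins[x[i + 1]])
    } else {
      if (i < L) rec("M", j + 1, i + 1, sc + tr[j, "DM"] + em[j + 1, x[i + 1]])
      rec("D", j + 1, i, sc + tr[j, "DD"])
    }
  }
  for (st in seq_len(L)) {
    for (k in seq_len(M)) rec("M", k, st, -log2(M) + em[k, x[st]])
  }
  best
}

# spec-rule overlap scan re-derived in R
oracle_find_overlap <- function(fseq, rseq, min_overlap, max_mm_rate) {
  rc <- revcomp(rseq)
  fv <- strsplit(fseq, "")[[1]]; rv <- strsplit(rc, "")[[1]]
  lf <- length(fv); lr <- length(rv)
  best <- NULL
  consider <- function(o, mt, readthrough) {
    if (is.null(best) || mt > best$mt ||
        (mt == best$mt && (o > best$o || (o == best$o && best$rt && !readthrough)))) {
      best <<- list(o = o, mt = mt, rt = readthrough)
    }
  }
  for (o in min_overlap:min(lf, lr)) {
    aseg <- fv[(lf - o + 1):lf]; bseg <- rv[1:o]
    mt <- sum(aseg == bseg & aseg != "N")
    if ((o - mt) / o <= max_mm_rate) consider(o, mt, FALSE)
    if (o < min(lf, lr)) {
      aseg <- rv[(lr - o + 1):lr]; bseg <- fv[1:o]
      mt <- sum(aseg == bseg & aseg != "N")
      if ((o - mt) / o <= max_mm_rate) consider(o, mt, TRUE)
    }
  }
  if (is.null(best)) NULL else best$o
}

# small toy profiles for the enumeration cross-checks
toy_profile <- function(which = c("uniform3", "gapped4"), seed = 21L) {
  which <- match.arg(which)
  aln <- switch(which,
    uniform3 = c("ACG", "ACG", "AAG", "CCG"),
    gapped4 = c("AC-GT", "ACAGT", "AC-GA", "AC-GT"))
  build_profile(aln, name = which, pseudocount = 0.5,
                calib_n = 100L, calib_len = 25L, seed = seed)
}

# shared default profile set (memoized inside the package)
test_profiles <- function() default_profiles(101L)
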