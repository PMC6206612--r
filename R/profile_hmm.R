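BASES <- c("A", "C", "G", "T")
TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
FLANK_NAMES <- c("SSU_tail", "R5.8S", "LSU_head")

#' Heuristic significance thresholds
#'
#' Staged significance thresholds in the spirit of accelerated profile-HMM
#' search: `f1` gates an ungapped diagonal prefilter, `f3` gates the final
#' local-Viterbi hit. All default to `1e-6`, an aggressive setting tuned for
#' abundant near-identical amplicon data. This implementation uses a single
#' prefilter stage, so `f2` is accepted for interface compatibility but has
#' no effect (a warning is emitted when it is changed from its default).
#'
#' @param f1,f2,f3 P-value thresholds in `(0, 1]`.
#' @return a validated threshold list.
#' @export
heuristic_thresholds <- function(f1 = 1e-6, f2 = 1e-6, f3 = 1e-6) {
  stopifnot(f1 > 0, f1 <= 1, f2 > 0, f2 <= 1, f3 > 0, f3 <= 1)
  if (f2 != 1e-6) {
    warning("f2 is accepted for compatibility but ignored: ",
            "this implementation has a single prefilter stage")
  }
  list(f1 = f1, f2 = f2, f3 = f3)
}

#' Build a nucleotide profile HMM from a gapped multiple alignment
#'
#' Columns with more than 50% gaps become insert states; the remaining
#' columns are match states. Emission and transition probabilities are
#' maximum-likelihood counts with an additive pseudocount. After
#' construction the model is calibrated: `calib_n` random sequences drawn
#' from the background distribution are scored with local Viterbi (and with
#' the ungapped prefilter statistic) and a Gumbel distribution is fitted to
#' each score set by maximum likelihood, giving the `(lambda, mu)` pairs
#' used for P-value and E-value conversion.
#'
#' @param alignment character vector of equal-length gapped sequences
#'   (`-` or `.` for gaps), a `DNAMultipleAlignment`/`DNAStringSet`, or the
#'   path of an aligned FASTA file.
#' @param name profile name, one of `"SSU_tail"`, `"R5.8S"`, `"LSU_head"`
#'   (free names are allowed for custom profiles).
#' @param pseudocount additive pseudocount for emissions and transitions.
#' @param calib_n number of random calibration sequences (>= 100).
#' @param calib_len length of each calibration sequence.
#' @param seed RNG seed for calibration (mandatory for reproducibility).
#' @return An object of class `profile_hmm`.
#' @export
build_profile <- function(alignment, name, pseudocount = 1,
                          calib_n = 1000L, calib_len = 150L, seed = 101L) {
  aln <- as_alignment_matrix(alignment)
  if (nrow(aln) < 2L) stop("profile alignment needs at least 2 sequences")
  ncolumns <- ncol(aln)
  if (ncolumns < 1L) stop("empty alignment")
  is_gap <- aln == "-" | aln == "."
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac <= 0.5)
  M <- length(match_cols)
  if (M == 0L) stop("alignment has no match columns (all columns > 50% gaps)")

  # background from observed residue frequencies, pseudocounted
  res <- aln[!is_gap]
  bg_counts <- table(factor(res[res %in% BASES], levels = BASES))
  background <- (as.numeric(bg_counts) + pseudocount) /
    (sum(bg_counts) + 4 * pseudocount)
  names(background) <- BASES

  # match emissions
  me <- matrix(0, M, 4, dimnames = list(NULL, BASES))
  for (k in seq_len(M)) {
    col <- aln[, match_cols[k]]
    cnt <- table(factor(col[col %in% BASES], levels = BASES))
    me[k, ] <- (as.numeric(cnt) + pseudocount) / (sum(cnt) + 4 * pseudocount)
  }

  # insert emissions pooled over all insert columns
  ins_res <- aln[, setdiff(seq_len(ncolumns), match_cols), drop = FALSE]
  ins_cnt <- table(factor(ins_res[ins_res %in% BASES], levels = BASES))
  insert_emissions <- (as.numeric(ins_cnt) + pseudocount) /
    (sum(ins_cnt) + 4 * pseudocount)
  names(insert_emissions) <- BASES

  # transition counts from each sequence's implied state path
  tc <- matrix(0, M, 7, dimnames = list(NULL, TRANS_NAMES))
  col_state <- integer(ncolumns)           # model position of each match col
  col_state[match_cols] <- seq_len(M)
  for (s in seq_len(nrow(aln))) {
    prev <- "M"; prev_pos <- 0L            # virtual begin treated as match 0
    for (cc in seq_len(ncolumns)) {
      if (col_state[cc] > 0L) {
        cur <- if (is_gap[s, cc]) "D" else "M"
        if (prev_pos >= 1L) {
          tc[prev_pos, paste0(prev, cur)] <- tc[prev_pos, paste0(prev, cur)] + 1
        }
        prev <- cur; prev_pos <- col_state[cc]
      } else if (!is_gap[s, cc]) {         # insert residue
        if (prev_pos >= 1L && prev != "D") {
          tc[prev_pos, paste0(prev, "I")] <- tc[prev_pos, paste0(prev, "I")] + 1
          prev <- "I"
        }
      }
    }
  }
  transitions <- matrix(0, M, 7, dimnames = list(NULL, TRANS_NAMES))
  groups <- list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))
  for (k in seq_len(M)) {
    for (g in groups) {
      cnt <- tc[k, g] + pseudocount
      transitions[k, g] <- cnt / sum(cnt)
    }
  }
  # last position has no outgoing core transitions; pin to deterministic exit
  transitions[M, ] <- c(1, 0, 0, 1, 0, 1, 0)

  consensus <- paste(BASES[apply(me, 1, which.max)], collapse = "")

  p <- structure(list(name = name, M = M,
                      match_emissions = me,
                      insert_emissions = insert_emissions,
                      transitions = transitions,
                      background = background,
                      consensus = consensus,
                      calibration = NULL),
                 class = "profile_hmm")
  p <- precompute_lodds(p)
  calibrate_profile(p, calib_n = calib_n, calib_len = calib_len, seed = seed)
}

as_alignment_matrix <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment)) {
    alignment <- Biostrings::readBStringSet(alignment)
  }
  if (methods::is(alignment, "DNAMultipleAlignment")) {
    alignment <- as.character(alignment)
  } else if (methods::is(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  alignment <- toupper(unname(alignment))
  widths <- nchar(alignment)
  if (!length(alignment)) stop("empty alignment")
  if (length(unique(widths)) != 1L) stop("aligned sequences differ in length")
  do.call(rbind, strsplit(alignment, ""))
}

precompute_lodds <- function(p) {
  p$lodds <- list(
    em = log2(sweep(p$match_emissions, 2, p$background, "/")),
    ins = log2(p$insert_emissions / p$background),
    tr = log2(p$transitions)
  )
  p
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm '", x$name, "': ", x$M, " match states\n", sep = "")
  cat("consensus: ", x$consensus, "\n", sep = "")
  if (!is.null(x$calibration)) {
    cat(sprintf("calibration: lambda=%.3f mu=%.3f (n=%d, len=%d)\n",
                x$calibration$lambda, x$calibration$mu,
                x$calibration$n, x$calibration$len))
    cat(sprintf("prefilter:   lambda=%.3f mu=%.3f\n",
                x$calibration$pre_lambda, x$calibration$pre_mu))
  }
  invisible(x)
}

seq_to_int <- function(seq) {
  code <- match(strsplit(seq, "")[[1]], BASES) - 1L
  code[is.na(code)] <- -1L   # N and friends: emission log-odds 0
  code
}

random_background_seqs <- function(n, len, background, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len, replace = TRUE, prob = background), collapse = "")
  }, character(1))
}

fit_gumbel <- function(scores) {
  # ML fit of a Gumbel (max) distribution; moment estimates as start values.
  # Degenerate score sets (tiny toy profiles can score every background
  # sequence identically) collapse to a sharp point null.
  beta0 <- stats::sd(scores) * sqrt(6) / pi
  if (!is.finite(beta0) || beta0 < 1e-6) {
    return(list(lambda = 1e6, mu = mean(scores)))
  }
  mu0 <- mean(scores) - 0.5772156649 * beta0
  nll <- function(par) {
    mu <- par[1]; beta <- exp(par[2])
    z <- (scores - mu) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- stats::optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  list(lambda = 1 / exp(fit$par[2]), mu = fit$par[1])
}

calibrate_profile <- function(p, calib_n = 1000L, calib_len = 150L, seed = 101L) {
  stopifnot(calib_n >= 100L)
  seqs <- random_background_seqs(calib_n, calib_len, p$background, seed)
  vit <- numeric(calib_n); pre <- numeric(calib_n)
  for (i in seq_along(seqs)) {
    x <- seq_to_int(seqs[i])
    vit[i] <- .viterbi_local_cpp(p$lodds$em, p$lodds$ins, p$lodds$tr, x)$score
    pre[i] <- .ungapped_best_cpp(p$lodds$em, x)
  }
  g <- fit_gumbel(vit)
  gp <- fit_gumbel(pre)
  p$calibration <- list(lambda = g$lambda, mu = g$mu,
                        pre_lambda = gp$lambda, pre_mu = gp$mu,
                        n = as.integer(calib_n), len = as.integer(calib_len),
                        seed = as.integer(seed))
  p
}

gumbel_pvalue <- function(score, lambda, mu) {
  # P(S > score) under the fitted Gumbel null
  -expm1(-exp(-lambda * (score - mu)))
}

#' Score-to-significance conversion for a calibrated profile
#'
#' @param profile a calibrated `profile_hmm`.
#' @param score bit score(s).
#' @return data frame with `p_value` and `e_value` (`e_value` is the P-value
#'   scaled by the number of calibration sequences, so the best score in a
#'   calibration-sized random set has E close to 1).
#' @export
score_significance <- function(profile, score) {
  cal <- profile$calibration
  if (is.null(cal)) stop("profile is not calibrated")
  p <- gumbel_pvalue(score, cal$lambda, cal$mu)
  data.frame(p_value = p, e_value = cal$n * p)
}

#' Local Viterbi search of a profile HMM on a read
#'
#' Finds the best-scoring local match (free entry into any match state with
#' a uniform entry cost, free exit after any match state) of the profile on
#' the read, in log2-odds bits against the profile background. The reported
#' `seq_start`/`seq_end` are envelope coordinates: the Viterbi alignment
#' footprint extrapolated to the full model span (clipped to the read), so
#' terminal substitutions that the local path shaves off do not shift the
#' boundary. The raw alignment footprint is kept in `ali_from`/`ali_to` and
#' `profile_start`/`profile_end`.
#'
#' @param profile a calibrated `profile_hmm`.
#' @param read DNA string (length >= 1).
#' @param thresholds [heuristic_thresholds()]; the hit is dropped when its
#'   P-value exceeds `f3`. Pass `NULL` to keep any hit (used for
#'   calibration and testing).
#' @return A one-row data frame (`profile`, `seq_id`, `seq_start`,
#'   `seq_end`, `profile_start`, `profile_end`, `ali_from`, `ali_to`,
#'   `bit_score`, `e_value`), or `NULL` when no hit passes.
#' @param seq_id identifier stored in the hit.
#' @export
viterbi_local <- function(profile, read, thresholds = heuristic_thresholds(),
                          seq_id = "") {
  if (!nzchar(read)) stop("viterbi_local: empty read")
  x <- seq_to_int(read)
  v <- .viterbi_local_cpp(profile$lodds$em, profile$lodds$ins,
                          profile$lodds$tr, x)
  if (is.na(v$score)) return(NULL)
  sig <- score_significance(profile, v$score)
  if (!is.null(thresholds) && sig$p_value > thresholds$f3) return(NULL)
  L <- length(x)
  env_start <- max(0L, v$seq_start - v$profile_start)
  env_end <- min(L, v$seq_end + (profile$M - v$profile_end))
  data.frame(profile = profile$name, seq_id = seq_id,
             seq_start = env_start, seq_end = env_end,
             profile_start = v$profile_start, profile_end = v$profile_end,
             ali_from = v$seq_start, ali_to = v$seq_end,
             bit_score = v$score, e_value = sig$e_value,
             stringsAsFactors = FALSE)
}

#' Ungapped diagonal prefilter
#'
#' Computes the best ungapped diagonal match-state score (the maximum
#' sub-segment sum of match emission log-odds over all diagonals) and tests
#' it against the `f1` significance threshold using the prefilter's own
#' Gumbel calibration. Used to short-circuit the full Viterbi on reads that
#' cannot contain the flank; conservativeness with respect to the final
#' `f3` gate is a tested contract, and the prefilter can be disabled.
#'
#' @inheritParams viterbi_local
#' @return `TRUE` if the read passes and full Viterbi should run.
#' @export
prefilter <- function(profile, read, thresholds = heuristic_thresholds()) {
  if (thresholds$f1 >= 1) return(TRUE)
  x <- seq_to_int(read)
  s <- .ungapped_best_cpp(profile$lodds$em, x)
  if (is.na(s)) return(FALSE)
  cal <- profile$calibration
  gumbel_pvalue(s, cal$pre_lambda, cal$pre_mu) <= thresholds$f1
}

#' Serialize a profile HMM to a text file
#'
#' Profiles are stored as JSON with emissions, transitions, background and
#' calibration, precise enough to round-trip.
#'
#' @param profile a `profile_hmm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  obj <- profile[c("name", "M", "consensus")]
  obj$match_emissions <- unclass(profile$match_emissions)
  obj$insert_emissions <- as.list(profile$insert_emissions)
  obj$transitions <- unclass(profile$transitions)
  obj$background <- as.list(profile$background)
  obj$calibration <- profile$calibration
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized profile HMM
#'
#' @param path file written by [write_profile()].
#' @return a `profile_hmm` object.
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  me <- matrix(as.numeric(obj$match_emissions), ncol = 4,
               dimnames = list(NULL, BASES))
  tr <- matrix(as.numeric(obj$transitions), ncol = 7,
               dimnames = list(NULL, TRANS_NAMES))
  p <- structure(list(name = obj$name, M = as.integer(obj$M),
                      match_emissions = me,
                      insert_emissions = setNames(as.numeric(obj$insert_emissions), BASES),
                      transitions = tr,
                      background = setNames(as.numeric(obj$background), BASES),
                      consensus = obj$consensus,
                      calibration = lapply(obj$calibration, function(v)
                        if (is.numeric(v) && v == round(v) && abs(v) < 2^31) v else v)),
                 class = "profile_hmm")
  p$calibration$n <- as.integer(p$calibration$n)
  p$calibration$len <- as.integer(p$calibration$len)
  p$calibration$seed <- as.integer(p$calibration$seed)
  precompute_lodds(p)
}
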