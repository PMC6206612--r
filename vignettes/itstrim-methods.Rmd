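---
title: "Methods: how itstrim locates and propagates ITS trim coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how itstrim locates and propagates ITS trim coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The eukaryotic internally transcribed spacer (ITS) is the standard fungal
barcode. It is amplified with primers sitting in the conserved flanking
genes — the SSU (18S) tail and the 5.8S gene for ITS1, the 5.8S gene and
the LSU (28S) head for ITS2 — so every read carries conserved sequence on
one or both ends. Leaving those conserved stretches on the reads degrades
taxonomic assignment, and exact-sequence-variant callers (DADA2, Deblur)
additionally require *FASTQ* input: trimming must preserve per-base
qualities, which rules out FASTA-only trimmers.

`itstrim` trims FASTQ reads to the spacer in five stages:

1. **merge** overlapping read pairs into single sequences with consensus
   qualities (paired layouts only);
2. **dereplicate** identical sequences, tracking abundance;
3. **cluster** the unique sequences greedily at high identity
   (default 99.5%);
4. **locate** the conserved flanks on each cluster representative with
   profile hidden Markov models (local Viterbi search) and convert the
   flank hits to trim coordinates;
5. **propagate** each representative's coordinates unchanged to every read
   in its cluster and write trimmed FASTQ.

Clustering is what makes the approach fast on amplicon data: abundant
near-identical reads share one HMM search. Propagating coordinates without
re-alignment is deliberate and has a known consequence: substitutions
between a member and its representative cannot move the trim point, but
insertions or deletions shift it by their length. That trade-off is
intrinsic to coordinate propagation; re-aligning members to their
representatives would change the semantics and is out of scope.

## Profile HMMs and boundary calling

Each flank model is a standard nucleotide profile HMM (match/insert/delete
states) built from a gapped multiple alignment: columns with more than 50%
gaps become insert states, the rest match states. Emissions and transitions
are maximum-likelihood counts with an additive pseudocount (default 1).
The background distribution is the alignment's pseudocounted residue
frequency.

Search is local Viterbi in log2-odds space: a path may enter at any match
state (uniform entry cost $\log_2 1/M$) and exit after any match state for
free (the "uni-local" approximation); flanking read sequence is emitted by
the background and contributes nothing. Scores are converted to
significance through a Gumbel null fitted by maximum likelihood to the
Viterbi scores of 1,000 random background sequences of length 150 drawn at
profile-build time from a fixed seed. The reported E-value is the Gumbel
P-value scaled by the number of calibration sequences, so the best score in
a calibration-sized random set has E near 1 (a property the tests check).

Two staged thresholds gate the search, both P-values with default
$10^{-6}$: `f1` gates an ungapped diagonal prefilter (the best
maximum-sub-segment sum of match log-odds over all diagonals, with its own
Gumbel calibration), and `f3` gates the final Viterbi hit. The prefilter is
a single stage, so the middle threshold `f2` of the three-stage convention
is accepted for interface compatibility and ignored with a warning.
Conservativeness of the prefilter — no read it rejects has a passing final
hit — is a tested contract, and the prefilter can be disabled.

**Envelope coordinates.** A local alignment happily shaves a mismatching
base off the end of a flank, which would shift the reported boundary by the
length of the shaved run even on error-free reads whenever a taxon carries
substitutions near a flank edge. Hit coordinates are therefore reported as
a model-span envelope: the Viterbi footprint extrapolated to the full
profile extent (`seq_end + (M - profile_end)`, and symmetrically at the
start), clipped to the read. Under substitution-only divergence this makes
boundaries exact; it is also consistent with consuming *envelope*
coordinates when importing HMMER3 `--domtblout` files. The raw alignment
footprint is kept alongside (`ali_from`/`ali_to`).

**Region geometry.** ITS1 runs from the end of the SSU-tail hit to the
start of the 5.8S hit; ITS2 from the end of 5.8S to the start of the LSU
head; ALL from SSU-tail end to LSU-head start. If exactly one relevant
flank is found the missing side falls back to the read edge and the
corresponding `*_flank_found` flag is set `FALSE` — primer-trimmed reads
may legitimately begin inside the spacer, and the flags let strict users
filter. If neither flank is found, or the interval is empty, the read is
excluded with the reason logged. The one-flank edge fallback is this
package's own design choice, surfaced through the flags.

All coordinates are 0-based half-open internally; conversion to 1-based
inclusive happens only at file-format boundaries (domtblout).

## Clustering and identity

Unique sequences are scanned in descending abundance (ties broken
lexicographically). Each sequence joins the *first* existing cluster whose
representative is at least `cluster_id` identical, else founds a new
cluster — first-fit centroid clustering in the greedy style of
VSEARCH-like tools. Greedy clusterers differ on first-fit versus best-fit
acceptance; first-fit is this package's documented choice (deterministic,
O(n·k)). At `cluster_id = 1` the clustering provably equals exact
dereplication.

Identity is computed from an optimal affine-gap global alignment as
matching columns over total columns, *including terminal gaps* in the
denominator (merged amplicons from one primer pair have near-equal spans,
and one documented convention beats an ambiguous one); `N` never matches.
The identity alignment uses match +2, mismatch −4, gap open −10, gap
extend −1 — gaps strongly discouraged, as appropriate for near-identical
sequences. Before aligning, a shared 8-mer count bound screens candidate
representatives: an alignment at identity $\ge t$ has at most
$(1-t)(|a|+|b|)$ non-match columns, each destroying at most $k$ of the
$|a|-k+1$ k-mer windows, so any true member must share at least
$(|a|-k+1) - k(1-t)(|a|+|b|)$ k-mers with its representative. The bound is
lossless at the permitted thresholds (0.98–1.00); tests verify the screen
never changes a clustering.

## Pair merging

The reverse read is reverse-complemented and every overlap placement of at
least `min_overlap` (default 12) bases is scanned in two geometries:
normal (insert at least as long as the reads) and read-through (insert
shorter; overhangs clipped). Among placements with mismatch rate at most
`max_mismatch_rate` (default 0.25), the most matching bases win, ties going
to the longer overlap. In the overlap, agreeing bases get quality
$\min(q_1+q_2, 41)$; disagreements keep the higher-quality base with
quality $|q_1-q_2|$ (ties keep the forward base at quality 2); `N` never
counts as a match and never wins. The merging stage this replaces does not
publish its parameters, so these defaults are this package's own and are
stated in the CLI help.

## Trim comparison

Two trimmings of the same reads are compared the way trimmer agreement is
conventionally measured: identical sequences count as offset (0, 0) without
aligning; differing ones are globally aligned (match +2, mismatch −1, gap
open −0.5, gap extend −0.1) and the start/stop offsets are the
alignment-column differences of the first/last aligned bases. The summary
is the fraction of reads whose larger absolute offset is within a window
(default 2 bases). Two conventions had to be fixed here. First, the printed
−0.5/−0.1 panel is interpreted as: the first base of a gap costs the
opening penalty and each further base the extension penalty (so a 1-base
gap costs 0.5). Second, optimal alignments can tie, and a fixed traceback
preference is not mirror-symmetric; each differing pair is therefore
aligned in a canonical orientation (lexicographically smaller sequence
first) and the offsets negated when swapped, which makes A-vs-B exactly
the negation of B-vs-A. Traceback preference is deterministic:
match/mismatch over gap-in-first over gap-in-second.

## The simulator

`simulate_amplicons()` generates the data every stage is tested against:
each taxon's insert is `SSU tail + ITS1 + 5.8S + ITS2 + LSU head`, with
flanks derived from the consensus of the bundled alignments and mutated
per taxon at `substitution_rate_taxa` (default 5%), and ITS regions drawn
uniformly at random (default lengths 100–160 bases) — hypervariable
regions of unrelated taxa are effectively random with respect to each
other. Reads carry independent per-base substitution errors (default
0.005) and Phred qualities from a discretized normal (mean 35, sd 3)
truncated to [2, 41]. Paired mode emits 2×300 reads (MiSeq v3 geometry);
the default segment lengths (60 + ITS1 + 140 + ITS2 + 60) keep the longest
insert at 580 bases so every pair can overlap by the 12-base minimum.
Ground truth is a per-read table of ITS1/ITS2 coordinates on the true
insert.

The bundled flank alignments are *synthetic* (generated, seeded, 8
sequences at 3% divergence with two mostly-gap columns) — stand-ins that
keep the package self-contained and licence-clean, not database
sequences; users can supply real SSU/5.8S/LSU alignments.

What the simulator deliberately does not emulate: quality-correlated
errors (errors are drawn independently of the quality string), indels in
reads, chimeras, platform-specific error profiles, length heterogeneity
beyond the configured ranges, and flank divergence with indels. Passing
tests therefore demonstrate correctness of the mechanics (coordinates,
propagation, thresholds, round trips) under substitution-only noise; they
do not certify boundary accuracy on real data, where indels near flank
edges and partially covered flanks occur.

## Numerical choices and degenerate inputs

* Gumbel fitting starts from moment estimates and maximises the likelihood
  with Nelder–Mead; score sets with essentially zero variance (tiny toy
  profiles can score every background sequence identically) collapse to a
  sharp point null rather than failing.
* The last model position's outgoing transitions are pinned to a
  deterministic exit; they are never used by the recursion.
* Reads are scanned in the given orientation; `--reverse-complement-scan`
  scans both and keeps the higher total bit score (merged amplicons from a
  fixed primer pair have fixed orientation, the flag covers protocol
  variants).
* Empty FASTQ files are valid and yield empty outputs; empty sequences are
  errors for alignment and identity; interleaved files with a trailing
  unpaired read are fatal.
* Quality encoding is fixed to Phred+33 internally; `qual_offset = 64`
  re-encodes on input rather than guessing from the byte range.

## Problem sizes used by the tests and the acceptance script

The simulation scales were chosen to exercise the pipeline at realistic
unique-sequence counts while keeping a full check run comfortable on one
core: boundary recovery uses 1,000 reads from 20 taxa; the
cluster-vs-per-read equivalence check uses 2,000 reads; clustering
soundness verifies 500 unique sequences at thresholds 0.98/0.995/1.00
against an independent aligner; the DP cross-checks enumerate all state
paths for profiles of up to 4 match states and reads up to 6 bases, and
200 random pairs up to length 10 for the aligner.

## Known limitations

* Trim coordinates are propagated without re-alignment (see above); at
  99.5% identity, members with indels relative to their representative are
  trimmed a few bases off.
* The Gumbel tail is extrapolated far beyond the calibration range at the
  default thresholds; this is standard practice but means the `f3` gate is
  effectively "real flank or nothing" rather than a finely calibrated
  significance level.
* The bundled profiles are synthetic; trimming real fungal reads requires
  building profiles from real flank alignments (`build_profile()` or the
  `build-profile` CLI subcommand), or importing coordinates from an
  external HMMER3 run via `parse_domtblout()`.
* Single-threaded by design; `--threads` is accepted for compatibility.
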