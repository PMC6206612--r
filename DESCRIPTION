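Package: itstrim
Title: Quality-Preserving Trimming of Fungal ITS Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trims fungal internally transcribed spacer (ITS1/ITS2) amplicon
    reads to the spacer region while preserving per-base quality scores, so
    that trimmed FASTQ files can feed exact-sequence-variant callers such as
    DADA2 or Deblur. Overlapping read pairs are merged with consensus
    qualities, merged reads are dereplicated and greedily clustered at high
    identity, conserved flanking-gene boundaries (SSU tail, 5.8S, LSU head)
    are located on cluster representatives with profile hidden Markov models
    using local Viterbi search, and each representative's trim coordinates
    are propagated to every read in its cluster. Includes a synthetic
    ITS-amplicon simulator with ground-truth boundary coordinates, a
    trim-agreement comparison module based on affine-gap global alignment,
    an HMMER3 domain-table import path, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
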