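Package: vecsite
Title: Transcription Factor Binding Site Search in Vector Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Embeds fixed-length DNA words (l-mers) as sparse indicator
    vectors over single nucleotides and proximal nucleotide pairs, and
    searches for transcription factor binding sites by scoring candidate
    words against query vectors in configurable subspaces.  Implements the
    negative-to-positive vector (NPV) and optimal discriminating vector
    (ODV) query constructions, two-subtype variants built on k-means
    clustering of embedded sites, position-specific scoring matrix (PSSM)
    and positional-background likelihood-ratio (ULPB) baselines, a nested
    cross-validation protocol with rank-based AUC and partial AUC,
    interval matching against ChIP-seq peaks, and a synthetic-data
    generator for first-order Markov backgrounds and planted motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
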