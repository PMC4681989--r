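Package: slimclust
Title: Progressive Clustering of Short Peptides into Motif Clusters with
    Profile Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies multiple sequence motifs in large, noisy short-peptide
    datasets such as next-generation-sequenced phage display selections.
    Unique sequences are seeded into small cores by greedy incremental
    clustering under a gapless, shift-limited substitution-matrix alignment;
    cores are then grown by alternating rounds of profile hidden Markov model
    extension (local Viterbi search of the unassigned sequence pool) and
    agglomerative cluster merging driven by local HMM-HMM alignment scores,
    with similarity thresholds relaxed between rounds. Hard diversity
    constraints (minimum number of match states, gap and information-content
    rules for match columns, alignment width and inner-gap caps) veto any
    insertion or merge that would make a cluster overly diverse. Emits
    per-cluster multiple sequence alignments, per-label copy-count matrices,
    and Kullback-Leibler clustering-quality statistics, and includes a
    planted-motif synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
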