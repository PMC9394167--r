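Package: aptashape
Title: Aptamer Pool Profiling of Plasma Samples by Branched-Selection Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for branched-selection SELEX experiments in
    which a trained RNA aptamer pool is selected once against each individual
    plasma sample and read out by paired-end sequencing. Covers demultiplexing,
    pair-mate joining, variable-region extraction, dereplication,
    edit-distance (Damerau-Levenshtein, optimal string alignment) clustering,
    pool-fraction normalization, per-aptamer ordinary-least-squares
    differential-enrichment testing with Benjamini-Hochberg correction,
    discriminatory-aptamer selection, sequence-family grouping, hierarchical
    sample clustering, and PCA sign-rule classification of samples into
    control, early-stage and late-stage groups. Includes a multinomial
    simulator of branched-selection sequencing data with planted group
    effects and ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
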