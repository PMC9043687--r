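Package: igomeNet
Title: Sequence-Graph Analysis of Antibody-Repertoire Mimotope Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing deep-panning mimotope libraries as sequence
    graphs: ingestion of phage-display reads into counted peptide libraries,
    longest-common-subsequence (LCS) similarity graphs with ROC-calibrated
    edge criteria, differential neighborhood and cluster detection between
    two cohorts using recursive Louvain community detection, per-cluster
    position-specific scoring matrix (PSSM) models for epitope and proteome
    scanning, mapping of external peptide libraries onto the graph,
    capture-recapture diversity estimation, and Miller-Madow entropy based
    low-complexity characterisation. Includes a synthetic-data generator
    that emulates mimotope libraries with planted cross-reactivity families
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
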