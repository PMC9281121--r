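Package: degronet
Title: Degron Prediction, E3 Motif Calculation, and Degradation Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Per-residue degron prediction from protein sequence with a
    bidirectional recurrent neural scorer trained on augmented degron
    windows; post-processing of residue score tracks into called degron
    intervals; Gibbs-sampling alignment of variable-length degron peptides
    into fixed-length cores; pseudocount log-odds position-specific scoring
    matrix (PSSM) construction with randomized cutoff calibration; E3
    ubiquitin ligase-substrate interaction prediction by maximal
    degron-motif matching; and degron-aware annotation of cancer missense
    mutations (region classes, recurrence, per-protein enrichment, and
    degron property-change flags). Includes seeded synthetic-data
    generators (proteomes, implanted degrons, interaction and mutation
    tables) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
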