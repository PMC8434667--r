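Package: tugentropy
Title: Entropy-Based Fall-Risk Screening from Timed-Up-and-Go Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification pipeline for screening
    community-dwelling elderly adults for fall risk from a single unsegmented
    tri-axial timed-up-and-go (TUG) acceleration recording. Computes statistic,
    multiscale-entropy (coarse-graining, sample entropy, complexity index) and
    permutation-entropy features; converts clinical test scores (TUG, short-form
    Berg balance scale, short portable mental status questionnaire) into binary
    fall-risk labels, singly and in multifactor combination; estimates
    cross-validated random-forest feature importance with top-k re-training and
    pooled out-of-fold AUC/precision/recall; and statistically compares models
    with and without multiscale-entropy features. Includes a seeded synthetic
    cohort generator with group-dependent signal complexity so the full pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    pROC,
    nortest,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pracma,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
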