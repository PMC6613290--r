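Package: noterisk
Title: Inpatient Violence Risk Assessment from Routinely Collected
    Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for assessing the risk of
    inpatient violence in psychiatric wards from free-text clinical notes.
    Covers cohort construction from admission, note and incident tables
    (episode merging, note-window selection, outcome labelling, word-count
    exclusions), unsupervised paragraph-vector document embeddings, a
    radial-kernel support vector classifier with a false-positive /
    false-negative balancing operating point, patient-grouped nested
    cross-validation with fold-averaged and pooled AUC, DeLong standard
    errors, confidence intervals and paired/unpaired AUC comparisons,
    pooled confusion metrics with relative risk, subgroup and cross-site
    transfer evaluation, and an exploratory term screen (chi-squared,
    Matthews correlation, bootstrap stability selection, Holm-Bonferroni).
    Includes a synthetic two-site electronic-health-record corpus
    generator with planted term-level signal so every stage can be
    validated without access to protected patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
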