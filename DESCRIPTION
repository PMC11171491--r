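Package: cxreval
Title: Evaluation of Ensembled Lesion Detectors on Chest Radiographs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating bounding-box detection algorithms on chest
    radiographs. Implements majority-vote ensembling of several object
    detectors with per-pathology score-threshold calibration, consensus
    ground truth from multiple annotators with box averaging, image-level
    confusion classification against the consensus reference, a metric panel
    (sensitivity, specificity, PPV, NPV, FPR, FNR) with Wilson score
    intervals, rank-statistic ROC AUC with stratified bootstrap confidence
    intervals, multi-reader multi-case (MRMC) aided-versus-unaided comparison
    statistics, Hanley-McNeil AUC sample-size calculation, and a fully
    seeded synthetic study generator so the whole pipeline can be exercised
    end to end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
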