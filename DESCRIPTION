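Package: ihhop
Title: Recurrence-Threshold Screening of Intermittent Oximetry Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects intermittent high-frequency high-amplitude oximetry
    patterns (IHHOP) in arterial oxygen saturation (SaO2) time series via
    recurrence quantification analysis. The central biomarker is the optimal
    recurrence threshold (the epsilon at which determinism rises fastest),
    computed in rolling windows. The package also implements the standard
    oximetry reference metrics (baseline-referenced desaturation events,
    oxygen desaturation index and density), Jenks natural-breaks classing of
    the biomarker, a binary-classifier/ROC screening harness for sleep-apnea
    labels, and a synthetic oximetry generator with ground-truth annotations
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    pROC,
    randomForest,
    Rcpp,
    rpart,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
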