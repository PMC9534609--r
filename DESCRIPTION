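Package: cardiofs
Title: Squirrel-Search Feature Selection and Hybrid CNN-LSTM
    Classification for Clinical Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Wrapper feature selection for clinical tabular data using the
    squirrel search algorithm augmented with elite opposition-based
    learning (EO-SSA), together with a four-channel attention CNN-LSTM
    classifier, preprocessing for Cleveland-dialect heart-disease tables
    (missing-value imputation, studentized-residual noise repair, min-max
    normalization), confusion-matrix metrics (sensitivity, specificity,
    precision, accuracy, F-score, Matthews correlation), and a repeated
    cross-validation evaluation harness. Includes a synthetic clinical
    data generator and standard benchmark objectives so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
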