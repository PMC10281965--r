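Package: cmscreen
Title: Tablet-Drawing Screening for Cervical Myelopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, feature extraction and diagnostic evaluation for
    shape-tracing pen recordings used to screen for cervical myelopathy.
    Generates synthetic two-group cohorts of stylus recordings (spiral,
    square-wave and triangular-wave tracings sampled at 120 Hz with device
    pressure units), extracts drawing time, average pressure and the
    spectral arc length (SPARC) smoothness of the pressure signal, fits the
    seven shape-combination support vector machine screening models with
    leave-one-out cross-validation and ROC analysis, and reproduces the
    study-style group-comparison statistics (median/IQR summaries,
    Mann-Whitney U, chi-square, Student's t).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
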