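Package: wristbow
Title: Bag-of-Words Analysis of Passive Wrist Accelerometry for
    Parkinson's Disease Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for distinguishing Parkinson's disease from healthy
    elderly subjects using week-long tri-axial wrist accelerometer
    recordings collected by passive monitoring.  Recordings are split into
    half-overlapping windows at multiple time scales (3 s to 15 min), each
    window is summarised by a ten-value descriptor set (vector magnitude,
    normalised RMS, movement dispersion and acceleration range per axis),
    and subjects are represented either by averaged descriptors or by a
    document-of-words model built from a K-medoid vocabulary with
    elbow-selected size.  Includes a genetic-algorithm feature selector, a
    repeated stratified cross-validation harness over six classifiers, the
    hypothesis tests comparing windowing strategies, feature-engineering
    methods and days of data, and a seeded synthetic cohort generator that
    emulates reduced movement amplitude and 4-6 Hz rest tremor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    e1071,
    rpart,
    randomForest,
    class,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
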