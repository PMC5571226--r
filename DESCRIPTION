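Package: abswarn
Title: Personalized Arrhythmia Advance Warning via Abnormal Beat Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Personalized electrocardiogram (ECG) monitoring for the advance
    detection of cardiac arrhythmias. Normal-to-abnormal beat degradation is
    modeled as a library of regularized least-squares FIR filters; the library
    is applied to an individual's average normal beat to synthesize potential
    abnormal beats, a compact two-channel 1D convolutional neural network is
    trained on real normal plus synthesized abnormal beats, and incoming beat
    streams are monitored with full confusion-matrix detection metrics.
    Includes a seeded synthetic ECG cohort generator so the whole pipeline is
    testable without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
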