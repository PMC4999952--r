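Package: vtpredict
Title: One-Hour-Ahead Ventricular Tachycardia Prediction from Heart Rate
    and Respiratory Rate Variability
Version: 0.1.0
Authors@R:
    person("CCU", "Analytics", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Extracts 11 heart-rate-variability and 3
    respiratory-rate-variability parameters from paired 5-minute ECG
    (lead II) and respiration windows, corrects ectopic beats with the
    integrated pulse frequency modulation (IPFM) model, and classifies
    windows as pre-ventricular-tachycardia versus control with a
    one-hidden-layer backpropagation perceptron.  Includes spectral
    analysis of the 7 Hz resampled RR tachogram (Welch periodogram,
    VLF/LF/HF bands), Poincare descriptors, breath-period statistics,
    stratified splitting, full evaluation (sensitivity, specificity,
    accuracy, PPV, NPV, ROC/AUC), and an IPFM-based synthetic cohort
    generator calibrated to published group statistics for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
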