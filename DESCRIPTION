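Package: szburden
Title: Seizure Burden Monitoring for Rapid-Response EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the burden of electrographic seizure activity in
    critical-care EEG recorded with a 10-electrode circumferential headband.
    Reads and writes EDF recordings, derives the 8-channel longitudinal
    bipolar montage, extracts power, morphology, entropy and cross-channel
    correlation features from nonoverlapping 10-second epochs, labels each
    epoch seizure/nonseizure with a transparent deterministic rule
    classifier, and converts epoch labels into a rolling 5-minute seizure
    burden trend with frequent (10%), abundant (50%) and continuous (90%)
    thresholds and status-epilepticus alerts.  Includes event-level scoring
    (sensitivity, specificity, negative predictive value, false detections
    per hour, exact binomial confidence intervals) and a seeded synthetic
    EEG generator emulating normal, diffusely slow, highly epileptiform and
    ictal recordings so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
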