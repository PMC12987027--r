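Package: wearqt
Title: Wearable 12-Lead ECG Stream Decoding and Ventricular
    Repolarization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for a wearable 12-lead electrocardiograph: bit-exact
    encoding and decoding of the device's fixed-length 40-byte telemetry
    packets with lead-off flags and stream resynchronization, derivation
    of the 12 standard leads from electrode potentials or from the eight
    transmitted channels, zero-phase signal conditioning (baseline, mains
    and muscle noise removal) with validity masking, R-peak detection and
    beat delineation (tangent-method T-wave end), rhythm and morphology
    metrics, and multi-lead ventricular repolarization analysis: per-beat
    QT, robust per-lead QT medians with eligibility rules, Bazett QTc and
    QT dispersion with explicit missing-value semantics. A ground-truth
    labelled synthetic ECG generator and device-stream simulator make the
    whole pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
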