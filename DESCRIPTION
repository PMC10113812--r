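Package: vstmtms
Title: Signal Detection and Bayes Factor Design Analysis for TMS Change-Detection Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis machinery for preregistered transcranial magnetic
    stimulation (TMS) studies of visual short-term memory using change-detection
    tasks. Provides a Jeffreys-Zellner-Siow (Cauchy-prior) Bayes factor engine
    for paired designs with prior-width robustness curves, Bayes factor design
    analysis with fixed-n and sequential (optional stopping) Monte-Carlo
    simulation, a signal-detection (d-prime) trial pipeline with participant
    quality control and reaction-time filtering, simulators for adaptive
    up-down staircase procedures, and a trial-level synthetic data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    withr,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
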