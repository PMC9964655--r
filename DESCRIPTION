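Package: emgrehab
Title: EMG-Driven Gesture Recognition and Performance Evaluation for
    Bilateral Hand Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale pipeline for evaluating threshold-based myoelectric
    control of a hand exoskeleton. Generates seeded synthetic two-channel
    forearm surface EMG (extensor digitorum, flexor digitorum) with
    gesture-locked activation bursts, 50 Hz mains interference and
    low-frequency drift; implements the real-time conditioning chain
    (50 Hz notch, 10 Hz high-pass, 50 ms RMS rectification, 2 Hz low-pass,
    decimation to 20 Hz, maximal-voluntary-contraction normalization),
    calibration of MVC values and muscular deactivation thresholds, the
    three-state boolean threshold gesture classifier, cross-correlation
    synchronization of target and recognized gesture series, L2-distance
    performance scoring, and the inference stage (multifactorial additive
    ANOVA, Duncan's multiple range test, homoscedasticity checks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    car,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
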