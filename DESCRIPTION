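Package: eggwave
Title: Gastric Slow-Wave Analysis for Multi-Channel Electrogastrography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for acquiring, simulating and analysing cutaneous
    electrogastrography (EGG) recordings made during driving-simulator
    studies of simulator sickness. Includes a digital twin of a
    three-channel analog front end (instrumentation amplifier plus
    second-order Sallen-Key high-pass and low-pass stages sampled at
    2 Hz), a seeded generator of ground-truthed synthetic EGG with
    dysrhythmic episodes and motion-artifact spikes, zero-phase
    Butterworth band-pass preprocessing, automatic channel selection and
    marker-based artifact excision, the five slow-wave features
    (dominant frequency, median frequency, crest factor, RMS and the
    normogastric Welch power fraction), Simulator Sickness Questionnaire
    scoring, and a session-level pipeline with FSR-based segmentation,
    cohort summaries and paired comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
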