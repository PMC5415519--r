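Package: frogrec
Title: Design and Evaluation of Automated Call Recognizers for Acoustic Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for building and validating automated call
    recognizers for bioacoustic monitoring, modelled on the workflow used
    for wood frog (Lithobates sylvaticus) chorus recordings. Simulates
    annotated synthetic choruses with hierarchical (site / recording /
    call) variability and calibrated signal-to-noise ratios, detects calls
    with a tunable spectrogram template recognizer (nine build variables,
    0-100 similarity scores), and evaluates recognizers with
    ROC/Youden-conditioned precision and sensitivity, a multi-syllable
    subsampling penalty, coefficient-of-variation sensitivity analysis of
    build variables, weighted Type-I/Type-II error optimization,
    beta-regression training-data scaling analysis with AICc model
    selection, and transferability evaluation across site/year dataset
    groups with BCa bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    glmmTMB,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
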