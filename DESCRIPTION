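Package: vasmeta
Title: Accuracy, Confidence and Metacognition from Double-Sided Visual Analog Scales
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing survey studies of statistical literacy and
    metacognition in clinicians. Decodes double-sided visual analog scale
    (VAS) responses into verdict and confidence, computes the
    distance-to-correct-answer score combining both, builds per-participant
    calibration and discrimination summaries, computes Bayesian positive and
    negative predictive values with conversion between conditional
    probability and natural frequency framings, classifies predictive-value
    estimates into correct and confusion-zone categories, and provides the
    classical contingency statistics (Yates-corrected chi-square, Welch t,
    Pearson r, Mann-Whitney, hypergeometric over-representation) with the
    conventions such surveys report. Ships a signal-detection based
    synthetic-respondent generator so the full pipeline is testable without
    access to raw survey data, plus a command-line interface for
    simulate/analyze/report workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
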