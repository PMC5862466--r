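Package: sahrisk
Title: Bayesian Risk Estimation and Lumbar Puncture Decision Support for
    Subarachnoid Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the probability of aneurysmal subarachnoid hemorrhage
    (SAH) in emergency department headache patients and supports the decision
    to perform a lumbar puncture (LP). Pre-test probability is computed with a
    Naive Bayes model over Ottawa SAH rule findings; post-test probability is
    obtained by likelihood-ratio updating with time-dependent non-contrast CT
    sensitivity (exponential decay or time-stratified) and CT angiography.
    Procedural risk factors raise the LP testing threshold through a weighted
    difficulty score, and the post-test probability is classified into
    green/yellow/red recommendation zones rendered as an SVG gauge with a
    logarithmic probability axis. A seeded synthetic-cohort simulator with
    known ground truth supports calibration checks, parameter recovery, and
    diagnostic strategy comparison. All model parameters live in a
    provenance-annotated JSON registry. Includes a command-line interface for
    single-patient scoring, simulation, and config validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
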