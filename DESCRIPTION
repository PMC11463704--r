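Package: splitprev
Title: Simulation and Bayesian Prevalence Analysis of Within-Participant
    Psychophysical Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the inferential workflow for establishing a
    within-participant perceptual effect across a population of observers:
    declarative psychophysics study designs with catch trials, simulation of
    trial-level report data from a perceiver/non-perceiver population
    mixture, per-subject exact one-sided binomial tests against commission
    or omission error baselines, Bayesian estimation of the population
    prevalence of the effect (maximum a posteriori estimate and highest
    posterior density interval, under a simple beta posterior and a
    test-calibrated model that accounts for the per-test false-positive
    rate), and the supporting group-level statistics (Welch two-sample
    t-tests from summary moments, simple regression, one-way ANOVA, and a
    BIC-approximate Bayes factor).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
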