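Package: tagdisc
Title: Hyperbolic Delay Discounting with Episodic Tags: Modelling,
    Adaptive Designs, and Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intertemporal-choice experiments in which
    delayed rewards may carry an "episodic tag" (an imagined future event).
    Implements the hyperbolic discounting model with softmax action
    selection and per-condition maximum-likelihood fitting, the adaptive
    indifference-point trial-schedule builder used to equate choice
    proportions across participants, a singleton visual-search index of
    flexible attentional control, autobiographical-interview detail
    scoring with inter-rater reliability, and the cohort-level statistics
    (repeated-measures ANOVA, covariate-adjusted correlations) that link
    attentional control to the episodic-tag effect.  A synthetic-cohort
    generator reproduces the statistical structure of all three data
    streams so every stage is testable without human data.
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
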