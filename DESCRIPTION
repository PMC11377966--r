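Package: mshale
Title: Multi-State Health Transitions and Disability-Specific Life Expectancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling disability trajectories in ageing cohorts
    observed as interval-censored panel data. Classifies survey observations
    into four health states (robust, IADL-disabled, BADL-disabled, dead),
    fits a continuous-time multi-state Markov model with proportional
    transition intensities and covariate hazard ratios by maximum
    likelihood, reports multi-year transition-probability tables, and
    estimates total and state-specific life expectancy between ages 50 and
    90 by stochastic microsimulation from fitted multinomial next-state
    models. Includes a synthetic panel-cohort generator with a known
    continuous-time Markov truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
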