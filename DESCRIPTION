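Package: beliefrl
Title: Belief-State Reinforcement Learning for Perceptual Decisions Under
    Asymmetric Reward
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and fitting tools for a confidence-weighted
    reinforcement-learning account of two-alternative perceptual decisions
    with blockwise-switching asymmetric rewards.  A noisy percept yields a
    Bayesian belief about stimulus side; beliefs multiply learned action
    values into expected values, an argmax rule selects the action, and a
    confidence-scaled reward prediction error updates the chosen value.
    The package also provides a hidden-Markov ideal-observer alternative
    that infers the reward block, simulation-based likelihood fitting with
    exhaustive grid search and cross-validated model comparison,
    confidence-history behavioral statistics with slow-bias correction,
    psychometric curve fitting, a trial-gain event-kernel regression for
    spike-count and fiber-photometry traces fitted by alternating least
    squares, and ground-truth synthetic-data generators for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
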