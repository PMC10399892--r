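Package: qshadow
Title: Initial Expectation Shadowing in Asymmetric Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian estimation tools for studying
    how the initial value expectation (Q0) of a Q-learning agent shadows the
    estimation of learning-rate asymmetry in two-armed bandit tasks. Provides
    generators for stable mini-block and reflecting random-walk reward
    schedules, softmax Q-learning agents with separate learning rates for
    positive and negative prediction errors, a hierarchical Bayesian fitting
    layer (probit-transformed parameters, MCMC with adaptive
    Metropolis-within-Gibbs updates), DIC and protected exceedance probability
    model comparison, a full parameter-recovery study over a Q0 x learning-rate
    grid, and model-free behavioral summaries (correct-choice rates,
    win-stay regression, preferred-response rates).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
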