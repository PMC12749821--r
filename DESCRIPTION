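Package: glmhmm
Title: Input-Driven GLM-HMMs for Trial-Based Choice Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits hidden Markov models of binary decision-making in which each
    latent state carries a Bernoulli generalized linear model (GLM) over trial
    covariates and state-to-state transitions are governed by a multinomial GLM
    over exponentially filtered trial-history regressors. Provides maximum a
    posteriori fitting by expectation-maximization with quasi-Newton M-steps,
    exact forward-backward inference, session-level cross-validation scored in
    bits per trial, a block-structured two-alternative forced-choice task
    simulator with ground-truth latent states, and derived state analyses
    (psychometric curves, dwell times, fractional occupancy, transition
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
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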