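Package: banditrnn
Title: Recurrent Networks for Trial-by-Trial Inference of Reinforcement-Learning Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reinforcement-learning agents with known, possibly
    time-varying parameters on two-armed bandit tasks and trains a recurrent
    neural network to jointly predict next actions and trial-by-trial latent
    parameters (learning rate, inverse temperature, perseveration, directed
    exploration). Ships Q-learning, Q-learning-with-perseveration and
    Kalman-filter/hybrid-exploration agent families, stationary
    maximum-likelihood and Bayesian particle-filter baselines, and evaluation
    tools (action cross-entropy, parameter recovery, stay-probability and
    exploration-dynamics analyses). All network code (two-stage gated
    recurrent units with classification, regression and action heads trained
    by backpropagation through time) is implemented in compiled code with no
    external deep-learning dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    readr
Config/testthat/edition: 3
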