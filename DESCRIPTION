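Package: rpeacc
Title: Accumulated Reward Prediction Errors in Behavior, Cortex, and Artificial Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying temporally accumulated reward prediction errors
    (RPEs) during goal-directed object manipulation. Provides a deep
    reinforcement-learning simulator (a proximal-policy-optimization
    actor-critic with a non-bootstrapped single-step RPE and n-step advantage
    accumulation) in a 2D arena with standard, intermittent-reward and split
    reward schedules; behavioral feature extraction from 10-ms trajectories
    (strokes, toward/away error detection, n-step error accumulation,
    peri-event lick histograms, empirical state-value maps); Poisson
    elastic-net encoding models with raised-cosine temporal bases,
    held-out pseudo explained variance, and error-neuron classification;
    population statistics (sequential-activity slope with permutation null,
    RPE-sign classification, reward-evoked activity, region summaries); and a
    synthetic-data generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
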