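Package: twostepeeg
Title: Hybrid Reinforcement Learning and Feedback-Locked EEG Analysis for a
    Two-Stage Markov Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a modified two-stage, one-decision Markov decision task
    with interleaved predictable (75/25) and random (50/50) transition
    structures and a fixed 70/30 reward structure; implements a hybrid
    model-free/model-based reinforcement-learning agent with eligibility
    trace, value forgetting, a transition-counter internal-model mechanism,
    and softmax choice with perseveration; fits the model per subject (MAP)
    and hierarchically by MCMC with split-Rhat diagnostics and WAIC model
    comparison; analyses stay/switch behavior with mixed-effects logistic
    regression; generates synthetic feedback-locked EEG epochs with
    configurable FRN, P3, theta and delta ground truth; quantifies these
    components (peak-to-peak FRN, mean-amplitude P3, Morlet time-frequency
    power with decibel baselining) and relates single-trial amplitudes to
    model-derived reward prediction errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    rlang,
    lme4,
    signal,
    stats,
    tibble
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
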