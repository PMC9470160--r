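Package: volinfer
Title: Bayesian Inference, Confidence and Changes-of-Mind in Volatile
    Reversal Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for two-alternative reversal
    tasks in which an observer either monitors a volatile stimulus category
    (uncontrollable condition) or samples stimuli through its own actions
    (controllable condition). Provides a seeded generative task simulator
    with von Mises stimulus categories and truncated-exponential reversal
    episodes; a normative hazard-rate observer with per-sample inference
    noise and a thresholded confidence readout corrupted by metacognitive
    noise and a switch-specific gain; reversal- and repetition-aligned
    psychometric curve fitting (asymptote, time constants, confidence drop,
    points of subjective equivalence); change-of-mind statistics including
    repeated-measures ANOVAs and MAP-regularized logistic regression;
    simulation-based model fitting with multi-start bounded search and a
    parameter-recovery harness; and particle filtering of latent prior
    belief and evidence direction conditioned on observed choices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
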