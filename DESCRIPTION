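Package: locodann
Title: Cross-Species Locomotion Feature Discovery with Attention-Based
    Domain-Adversarial Networks
Version: 0.1.0
Authors@R:
    person("Locodann", "Developers", email = "locodann@example.org",
           role = c("aut", "cre"))
Description: Discovers locomotion features shared across animal species
    (domains) that differ hugely in spatial and temporal scale. Converts 2D
    trajectories into normalized speed time-series, trains a 1D-convolutional
    classifier with an attention block and two domain predictors behind
    gradient reversal layers (three-phase adversarial training), explains the
    learned attention and classification with surrogate decision trees over
    interpretable rolling-window features, and validates the resulting
    hypotheses with two-sample location tests (Welch, Brunner-Munzel). Ships a
    synthetic two-species cohort generator with planted locomotion signatures
    so the whole pipeline is testable without animal data, plus command-line
    entry points for simulate/preprocess/train/explain workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
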