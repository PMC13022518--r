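Package: rewpun
Title: Reward and Punishment Learning: Task Simulation, Model Fitting, and
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how punishment contexts modulate reward
    learning. Provides a simulator for a probabilistic reward/punishment
    choice task with mixed- and single-valence blocks, a Rescorla-Wagner
    Q-learning model family with separate learning rates for positive and
    negative prediction errors, constrained maximum-likelihood and
    maximum-a-posteriori fitting, random-effects Bayesian model selection
    with protected exceedance probabilities, parameter-recovery and
    posterior-predictive validation, behavioral summaries with
    repeated-measures ANOVA, event-related BOLD percent-signal-change
    analyses binned by punishment history, and a multilevel kernel density
    (MKDA) coordinate-based meta-analysis with permutation family-wise
    error control and bootstrap balancing of unequal study categories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
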