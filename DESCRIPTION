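Package: opstrat
Title: Strategy Analysis for Operant Two-Choice Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing behavioural strategies in operant two-choice
    (touchscreen) discrimination learning. Provides a generative simulator of a
    three-phase cued two-alternative task with correction trials, enforced
    cue-position shifts and ambiguous probe trials; a family of behavioural
    agents (outcome-rule, cue-rule, reinforcement-learning, side-bias and
    random policies); descriptive win-stay/lose-shift and cue-rule accuracy
    metrics; agent-based bootstrap null distributions for rule-consistent
    performance; cue-state and outcome-state reinforcement-learning models
    with a hybrid Rescorla-Wagner/Pearce-Hall update and multistart
    maximum-likelihood fitting; and random-effects Bayesian model selection
    with exceedance probabilities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
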