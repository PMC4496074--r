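Package: mazecbt
Title: Exploration-Based Cognitive Bias Testing for Mice on the Radial Arm Maze
Version: 0.1.0
Authors@R:
    person("Maze", "CBT Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for an exploration-based cognitive (judgement)
    bias test for laboratory mice on an eight-arm radial maze. Provides the
    maze contingency state machine (light, white noise, pellet delivery),
    conversion of tracking exports into zone occupancies, arm visits and
    per-trial quality control, the reference / positive / near-positive
    arm-preference scores, a home-cage observation layer (one-zero time
    sampling and stereotypy bout classification), the study's statistical
    models (linear mixed models with litter and cage random intercepts,
    Bonferroni-corrected paired t-tests, Kruskal-Wallis), and a synthetic
    cohort simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    numDeriv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
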