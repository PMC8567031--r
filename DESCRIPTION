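Package: skillbound
Title: Bayesian Skill-Change Boundaries for Robot-Guided Motor Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide, before training, whether a person is likely to
    benefit from robot-guided (haptic) motor training. Computes per-trial
    position and velocity tracking errors from 2-D circle-drawing
    trajectories, fits four hierarchical Bayesian models of before/after
    skill change (pooled, varying slope, varying intercept, varying
    intercept-and-slope with an intercept-slope coupling), compares them by
    WAIC under leave-one-subject-out refitting, derives the initial-skill
    boundary gamma with its 94% credible interval from the coupling
    relation, and classifies held-out subjects as predicted responders or
    non-responders. Includes a synthetic-data generator emulating the study
    design (20 subjects, 2 sessions, 15 trials) for end-to-end testing,
    ggplot2 visualisations, and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
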