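Package: rosmod
Title: Moderated Regression Probing of Work-Environment by
    Stress-Reactivity Interactions
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether a biological moderator (hair
    cortisol content, a proxy for stress reactivity) changes the effect of
    work-environment scales on burnout outcomes according to the
    diathesis-stress, differential-susceptibility, or vantage-sensitivity
    model.  Covers Job Content Questionnaire and Maslach Burnout Inventory
    scale scoring, expectation-maximization imputation, distributional
    audits, four-step moderated hierarchical regression with R-squared
    change tests, Johnson-Neyman region-of-significance probing,
    proportion-of-interaction and proportion-affected indices, pattern
    classification, and a synthetic-cohort generator with plantable
    interaction regimes for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
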