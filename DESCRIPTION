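Package: effortdisc
Title: Physical Effort Discounting in Reach Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how humans discount physical effort when
    choosing between arm movements. Implements a hierarchical Bayesian
    probit choice model in which the subjective effort of a reach against
    a resistive force follows a power law with offset, and choices between
    a repeated reference action and a single test action depend on one of
    four competing utility transforms of effort (log-difference,
    difference, hyperbolic, hyperbolic-log). Includes an adaptive
    one-up one-down staircase task engine for two binary-choice reaching
    experiments, a synthetic-cohort generator producing stochastic
    observers, WAIC-based model comparison, equivalent-force (point of
    subjective equality) curves with credible bands, and a physics layer
    for the haptic force generation (virtual mass-spring-friction) and a
    planar two-link arm inverse-dynamics model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
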