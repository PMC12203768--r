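Package: reclamp
Title: Simulation and Analysis of Relearning in Visuomotor Clamp Adaptation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying attenuation of implicit sensorimotor adaptation
    upon relearning. Builds machine-readable protocols for five visuomotor
    error-clamp experiment designs (relearning after standard, no-feedback, or
    gradual-rotation washout, and learning after extended veridical-feedback
    baselines in one or several movement contexts), simulates closed-loop
    cohorts with a context-tagged state-space learner subject to anterograde
    interference from discrepant feedback, preprocesses trial-level reach
    angles into cycle-averaged series and aftereffect measures, and provides
    the statistical machinery used for such data: cluster-based permutation
    tests with max-statistic family-wise error control (paired-t and
    regression-slope variants), JZS Bayes factors for t tests, Greenhouse-
    Geisser repeated-measures ANOVA, random-slope linear mixed models, and
    noncentral-t power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
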