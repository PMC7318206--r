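Package: quitcea
Title: Trial-Based and Lifetime Cost-Effectiveness Analysis of Smoking
    Cessation Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the economic evaluation of smoking cessation aids
    from a health-service perspective. Implements within-trial
    cost-effectiveness analysis (treatment costing from session and
    product logs, quality-adjusted life-years by area under the utility
    curve, multiple imputation by chained equations with predictive mean
    matching and Rubin's-rules pooling, regression-adjusted incremental
    costs and effects, non-parametric bootstrap, cost-effectiveness
    planes and acceptability curves) and a three-state (smoker,
    ex-smoker, dead) lifetime Markov cohort model with
    smoking-attributable costs, discounting and probabilistic
    sensitivity analysis using moment-matched beta and gamma parameter
    distributions. A synthetic-trial generator reproduces the
    statistical structure of a two-arm cessation trial so that every
    stage of the pipeline can be exercised without access to
    individual-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
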