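Package: trialcea
Title: Trial-Based Cost-Effectiveness Analysis for Cluster-Randomised
    School Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for economic evaluation alongside
    cluster-randomised trials of school-based prevention programmes:
    unit costing of pupil-reported public-sector service use with
    piecewise-linear interpolation over survey gaps and annual
    discounting, programme (intervention) costing with delivery
    scenarios, covariate-adjusted incremental cost and effect
    estimation with school-level cluster bootstrap, cost-effectiveness
    planes, acceptability curves and dominance decision rules, one-way
    sensitivity analyses including multiple imputation by chained
    equations, and a synthetic cluster-RCT generator with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
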