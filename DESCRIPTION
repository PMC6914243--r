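Package: blendcea
Title: Trial-Based Cost-Effectiveness Analysis of Blended Versus Standard
    Psychotherapy
Version: 0.1.0
Authors@R:
    person("blendcea", "maintainers", email = "maintainers@blendcea.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for trial-based cost-effectiveness analysis
    of a two-arm psychotherapy trial with repeated assessments: derivation of
    clinical outcomes (reliable change index, treatment response, remission,
    quality-adjusted life-years from EQ-5D utilities), resource-use costing
    from societal and health-care-provider perspectives with cumulative-cost
    interpolation, baseline-adjusted linear and logistic mixed models for
    incremental costs and effects, Monte Carlo propagation to incremental
    cost-effectiveness ratios, cost-effectiveness planes and acceptability
    curves, sensitivity analyses, and a sample-size simulation for
    acceptability-curve stability. Includes a synthetic two-arm trial
    generator with covariate-dependent dropout so the whole pipeline is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
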