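Package: margstd
Title: Marginal Odds and Hazard Ratios by Regression Standardization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariate-adjusted estimators of marginal causal effect measures
    for noncollapsible models. Implements regression standardization of a
    conditional logistic fit to the marginal log odds ratio (Zhang's method),
    and a simulation-based marginalization of conditional Cox log hazard
    ratios under right censoring, including mimicry of the observed censoring
    mechanism. Provides inverse-probability-of-treatment-weighted comparators,
    nonparametric bootstrap standard errors and percentile confidence
    intervals, characteristic collapsibility functions with an
    exact-integration oracle for marginal effects, synthetic trial and cohort
    generators, and a simulation-study harness with Monte Carlo error
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
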