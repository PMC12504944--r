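Package: causaltri
Title: Triangulating Causal Treatment-Effect Estimators for Observational Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triangulating causal treatment-effect estimates from
    two-period observational data with binary outcomes. Implements confounder
    adjustment ('Corrected as Treated'), propensity-score matching, two-stage
    instrumental-variable and control-function estimators, logistic
    difference-in-difference regression, and prior-outcome-augmented IV/CF
    variants that use the prior-outcome-by-instrument interaction as a new
    instrument. All estimators report average marginal effects on the risk
    difference scale. A generalized Cochran's Q statistic with nonparametric
    bootstrap covariance quantifies the dissimilarity of correlated estimates.
    Includes a scenario-based data-generating simulator with known ground-truth
    risk difference, Monte-Carlo study orchestration with Morris-style
    performance metrics, a provider-preference instrument builder, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
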