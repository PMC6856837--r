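Package: miprop
Title: Combining Multiple Imputation and Propensity Scores in Simulation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Monte Carlo simulation framework for comparing the Across and
    Within approaches to combining multiple imputation by chained equations
    with propensity-score adjustment. Generates synthetic cohorts with
    confounded binary exposures, continuous or binary outcomes and missing
    confounder data (MAR or MNAR), imputes by chained equations, estimates
    propensity scores per imputation, and adjusts by inverse probability of
    treatment weighting, standardized mortality ratio weighting, greedy
    caliper matching or decile stratification, with estimated-propensity
    sandwich (Lunceford-Davidian) and robust standard errors. Replicate
    estimates are pooled by Rubin's rules and aggregated into bias, mean
    square error, Monte Carlo standard deviation, average standard error and
    confidence-interval coverage summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
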