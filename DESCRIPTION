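Package: opencohortpower
Title: Power and Sample Size for Open-Cohort Longitudinal Cluster Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-stage power and sample size calculations for stepped wedge,
    cluster crossover and parallel longitudinal cluster randomized trials whose
    sampling structure is an open cohort: the number of participants measured in
    each cluster-period is constant, but individual participants contribute
    variable numbers of measurements. Implements a unified design effect indexed
    by the churn rate (the expected proportion of participants lost between a
    pair of periods), covariance models for cluster-period means under
    block-exchangeable and discrete-time-decay correlation structures,
    generalized least squares variances of the treatment effect estimator,
    rotation ("in-for-p"), core-group, closed-population and Beta-distributed
    churn sampling schemes, moment-matching conversion of autocorrelations
    estimated without decay into their decay-model analogues, and a Monte Carlo
    simulator of open-cohort trials that verifies the analytic results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
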