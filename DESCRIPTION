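Package: oagrisk
Title: Simulation and Genetic Risk Analysis for Incident Open-Angle Glaucoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analysis of incident open-angle glaucoma
    within a longitudinal population cohort. Generates synthetic cohorts with
    realistic baseline covariate distributions, Hardy-Weinberg genotypes at
    reported glaucoma risk loci, and incident case status driven by a logistic
    risk model; performs univariate allelic association tests, covariate-adjusted
    additive logistic regression, joint multivariate modelling with collinearity
    diagnostics, and Bonferroni control; computes Cochran-Armitage trend-test
    power from penetrances anchored to population prevalence; and ranks variable
    importance with an exhaustive-subset neural-network ensemble scored by
    classification error on held-out data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
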