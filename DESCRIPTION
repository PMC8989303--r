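Package: stabml
Title: Stabilized Machine Learning Workflows for Small Clinical Cohorts
Version: 0.1.0
Authors@R: person("TRACK", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reproducibility-hardened machine-learning workflows for small
    clinical datasets. Implements repeated k-fold cross-validation
    "projects" with grouped, stratified partitioning; pluggable
    preprocessing+estimator blueprints (quintile-binned L2 logistic
    regression, gradient-boosted trees, majority-class benchmark);
    cross-project aggregation with stability metrics (standardized
    performance confidence-interval width, feature rank instability);
    stabilized permutation feature importance and partial dependence;
    expert-protected backward feature elimination; intraoperative
    blood-pressure threshold feature engineering with a threshold sweep;
    external-validation scoring and population-drift auditing via the
    population stability index and cohort clustering; and a seeded
    generator of spinal-cord-injury-like synthetic cohorts for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    uwot,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
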