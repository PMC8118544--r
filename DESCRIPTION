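Package: msceapc
Title: Multistage Clonal Expansion Models of Cancer Incidence with
    Regularized Age-Period-Cohort Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Likelihood-based fitting of multistage clonal expansion (MSCE)
    models to registry-style cancer incidence tables, with smooth historic
    period and birth-cohort trends acting directly on the biological model
    parameters rather than as proportional-hazards multipliers.  The model
    couples the stochastic onset of a premalignant field-defect with a
    two-stage clonal expansion to malignancy and a fixed clinical lag.  The
    package provides the analytic hazard and survival functions, Poisson
    likelihoods and deviances on age-by-period strata, maximum-likelihood and
    adaptive Metropolis-Hastings estimation, an individual-level stochastic
    simulator used to validate the analytic hazard, and a generator of
    synthetic SEER-like incidence tables with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
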