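Package: twinace
Title: Twin ACE Variance-Component Analysis of Intervention Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for longitudinal twin studies in
    which an intervention is embedded between repeated assessments. Provides
    a seeded simulator for monozygotic/dizygotic twin cohorts with an exact
    four-stage Cholesky ACE covariance structure, scale scoring and
    preprocessing (baseline standardization, van der Waerden normal scores,
    age/sex residualization), twin variance-component estimation (intraclass
    correlations, Falconer moment estimates, maximum-likelihood univariate
    and multivariate Cholesky ACE models with profile-likelihood confidence
    intervals), derived stability/innovation statistics, piecewise multilevel
    growth models for the mean intervention response, and Monte-Carlo power
    analysis for the classical twin design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
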