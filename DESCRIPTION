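Package: icpdx
Title: Per-Case Reliability Diagnostics for Predicted Intracranial Pressure Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reliability analysis of machine-learning-derived intracranial
    pressure (ICP) prediction distributions at the level of a single case.
    Estimates the probability density of each case's per-vessel prediction
    sample, computes the definite-integral reliability statistic DI_ICP
    (probability mass within +/- 1 cm water of the predicted median),
    moment and normality diagnostics (Lilliefors Kolmogorov-Smirnov and
    Anderson-Darling statistics), Shannon entropy of the binned
    distribution, the two-sample Kolmogorov-Smirnov concordance between
    arterial and venous predictions, and Cullen-Frey skewness-kurtosis
    distribution classification. Cohort-level summaries link these
    diagnostics to prediction error through correlation and univariate-F
    analyses, with a synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fitdistrplus,
    knitr,
    nortest,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
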