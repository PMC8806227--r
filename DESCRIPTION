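Package: pairhazard
Title: Rank-Based Gene-Pair Prognostic Signatures for Survival Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates prognostic signatures from within-patient
    binary gene-pair comparisons. Provides robust variance filtering of
    candidate genes across cohorts, exhaustive gene-pair scoring that is
    invariant to any within-sample monotone transform of expression,
    univariate Cox screening, LASSO-penalized Cox model selection,
    time-dependent ROC cutoff calibration, frozen-cutoff external validation
    with subgroup and multivariable Cox analyses, reference-based immune-cell
    deconvolution with permutation p-values, and a two-cohort synthetic data
    generator with planted prognostic pairs for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
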