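Package: nenplasma
Title: Plasma Metabolomics Biomarker Discovery for Pulmonary
    Neuroendocrine Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a targeted plasma-metabolomics
    biomarker-discovery workflow for pulmonary neuroendocrine neoplasms
    (carcinoid tumors, small-cell and large-cell neuroendocrine
    carcinomas). Provides a seeded synthetic cohort generator emulating a
    multi-group case-control study design, missingness filtering and
    z-score standardization, bootstrap-resampled Mann-Whitney marker
    selection with Bonferroni-corrected median p-values, fold-change
    direction calls and Venn overlaps across subtypes, class-weighted
    lasso/ridge/elastic-net logistic models tuned by repeated stratified
    cross-validation with backward elimination, and metabolite-set
    enrichment via a generalized-linear-model global test Q-statistic
    with permutation p-values over a GMT pathway library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
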