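Package: varliab
Title: Liability-Scale Effect Sizes of Rare Variants in Sex-Stratified Trio Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact-binomial burden and transmission-disequilibrium tests on de
    novo and inherited rare-variant counts from trio and case-control cohorts,
    conversion of observed-scale enrichment into liability-scale effect sizes
    under sex-specific liability threshold models (including phenotype-scaled
    prevalences and unequal-variance variants), covariate-matched gene-set
    permutation nulls, inverse-variance meta-analysis with tiered multiplicity
    adjustment, and a generative trio-cohort simulator under the same liability
    model so every stage can be validated by parameter recovery without access
    to controlled individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
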