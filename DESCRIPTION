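Package: gutdea
Title: Gut Microbiota Efficiency Analysis via Data Envelopment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A holistic, frontier-based evaluation of how efficiently an
    individual's lifestyle (dietary fiber, fatty acids, alcohol, smoking,
    physical activity, sleep) is converted into a beneficial gut microbiota
    profile (relative abundances of lactic-acid genera and Faith's
    phylogenetic diversity). Implements the output-oriented
    Banker-Charnes-Cooper (variable returns-to-scale) data envelopment
    analysis model by linear programming, peer-based lack-of-output
    decomposition for personalized targets, two-sided censored (Tobit)
    regression of efficiency scores on covariates, chained-equation multiple
    imputation with predictive mean matching and Rubin's-rules pooling, and
    a Gaussian-copula synthetic cohort generator that emulates the marginal
    distributions, zero-inflation and correlation structure of a
    population-based microbiome cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
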