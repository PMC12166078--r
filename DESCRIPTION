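Package: musicom
Title: Linking Early Musicality to Later Communication with Polygenic
    Scores and Structural Equation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-stage analysis framework for developmental cohort
    studies of musicality and communication. Stage 1 screens ordinal
    musicality predictors against continuous communication outcomes via
    covariate-adjusted incremental R-squared, with Bonferroni and
    spectral-decomposition (effective number of tests) corrections and a
    split-half EFA-to-CFA latent-structure discovery pipeline. Stage 2
    computes polygenic scores from external weight tables, tests their
    association with ordinal phenotypes by proportional-odds regression
    with incremental Nagelkerke R-squared, and removes genetic
    confounding by a GWAS-by-subtraction Cholesky decomposition of
    summary statistics. Stage 3 embeds a polygenic score in the
    confirmed factor model and decomposes factor-to-factor associations
    into genetically shared (a*b) and direct (c) components. Includes a
    normal-theory maximum-likelihood covariance-structure engine with
    fit indices and bootstrap standard errors, and a synthetic-cohort
    generator emulating the assumed data structure for fully
    reproducible desk-scale runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
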