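Package: ldlrm
Title: Recursive Mixed Models from Multiple-Trait Animal Models via LDL'
    Transformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian inference for multiple-trait pedigree ("animal")
    models with heavily patterned missing records, and post-hoc conversion
    of every posterior sample of the genetic (G) and residual (R)
    covariance matrices into the parameters of likelihood-equivalent
    recursive (structural equation) models through LDL' and block-LDL'
    factorizations. Includes pedigree utilities (numerator relationship
    matrix and its sparse inverse), a Gibbs sampler with data augmentation
    of missing phenotypes implemented in C++, a forward simulator for
    synthetic pedigrees and phenotypes, posterior summaries
    (heritabilities, correlations, structural coefficients, effective
    sample sizes), and a reproducible simulate-fit-transform-summarize
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
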