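Package: ltbayescpi
Title: Joint Genomic Prediction of a Continuous and a Threshold Trait with
    Bayesian Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bivariate linear-threshold Bayesian mixture models for genomic
    selection. Implements LT-BayesCpi, a spike-and-slab (BayesCpi-type) model
    that jointly analyses one continuous trait and one binary threshold trait
    with a shared per-SNP inclusion indicator and a bivariate-normal slab, plus
    its single-trait special cases BayesCpi (continuous) and BayesTCpi
    (threshold, via latent liabilities). The Gibbs sampler handles the fixed
    residual variance of the binary trait through conditional inverse-Wishart
    draws (Korsgaard-type algorithm). Includes a forward-in-time two-trait
    population simulator (mutation-drift equilibrium history, Haldane
    recombination, pleiotropic and trait-specific QTL groups), evaluation of
    genomic estimated breeding values against true breeding values (accuracy,
    bias slope with liability-scale rescaling), and a scenario-grid experiment
    runner with replicate aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    truncnorm,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
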