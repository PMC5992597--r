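Package: stmgrn
Title: Meta-Analysis, Consensus Bayesian Networks and Boundary-Patterning
    Models for the STM Regulatory Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for reconstructing the gene-regulatory
    neighbourhood of the shoot-meristem regulator STM and for modelling
    boundary patterning in the shoot apical meristem. Provides Fisher
    inverse chi-squared meta-analysis of differential-expression p-values
    with Benjamini-Hochberg and Storey q-value control, UPGMA and k-means
    clustering, hypergeometric gene-set enrichment, three-state
    discretisation of expression compendia, BDeu-scored Bayesian-network
    structure search by simulated annealing with consensus-network
    construction and influence signs, and a reaction-diffusion ODE model
    of the STM-CUC1-miR164c-TCP circuit on a one-dimensional cell file
    with perturbation variants and local sensitivity analysis. A
    synthetic-data module generates ground-truth fixtures for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    deSolve,
    yaml,
    xml2,
    ggplot2,
    generics,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
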