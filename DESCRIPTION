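Package: ginet
Title: Directed Genetic Influence Networks from Multi-Phenotype Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers directed genetic-interaction ("influence") networks from a
    genotyped population measured for two or more partially pleiotropic
    quantitative phenotypes. Phenotypes are standardized and factored into
    orthogonal composite phenotypes (eigentraits) by singular value
    decomposition; single-locus scans select strong-effect covariates; every
    locus pair is fit with main effects and an interaction term; interaction
    coefficients are reparametrized into activity changes and directed,
    signed variant-to-variant influence coefficients with delta-method error
    propagation; significance is calibrated by tandem genotype permutations
    with Holm step-down adjustment; recomposed variant-to-phenotype effects
    are averaged over pairwise models and assembled, with the influences,
    into a significance-filtered directed network. Includes an expression
    mode (SVD of a gene-expression matrix with appended phenotype rows, mode
    gene sets, and enrichment tests) and a synthetic-data generator with
    known ground-truth networks for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
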