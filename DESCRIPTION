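Package: crossgp
Title: Multi-Population Genomic Prediction with Bayesian Variable Selection and GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying the accuracy of
    across-population genomic prediction. Simulates multi-population SNP
    genotypes with linkage disequilibrium, allele-frequency divergence and
    half-sib family structure, together with quantitative traits whose QTL
    allele substitution effects are correlated across populations. Predicts
    genomic estimated breeding values with a Bayesian stochastic search
    variable selection (SSVS) Gibbs sampler and with GBLUP based on REML
    variance components, estimates the number of independent chromosome
    segments from genomic and pedigree relationship matrices, and
    orchestrates replicated prediction scenarios with cross-validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
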