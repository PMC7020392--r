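Package: gsqpred
Title: Two-Stage GWAS-Informed Bayesian Genomic Prediction for Open-Pollinated Progeny Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, quality control and analysis toolkit for genomic
    selection in open-pollinated forest-tree progeny trials genotyped with
    low-density SNP panels. Implements single-site Gibbs samplers for the
    Bayes A, Bayes B, Bayes C-pi and Bayesian ridge regression marker priors
    extended with correlated Gaussian random effects (a pedigree polygenic
    term and a QTL-genotype term whose covariance is a realized relationship
    over GWAS-significant markers), an EMMA-style mixed-model association
    scan with Benjamini-Hochberg significance calling, pedigree and marker
    relationship matrices, descriptive population genetics (heterozygosity,
    Weir-Cockerham F_ST, composite LD), deviance-information-criterion model
    comparison, k-fold cross-validated predictive ability, and a synthetic
    data generator emulating a multi-provenance half-sib progeny trial.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
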