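Package: snpformer
Title: Genomic Prediction from SNP Genotypes with a Self-Supervised Transformer and GBLUP Baselines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage genomic prediction of quantitative traits from SNP
    genotypes: an encoder-only Transformer is pre-trained on unlabelled
    genotype sequences with a masked 6-mer prediction objective and then
    fine-tuned to regress phenotypes from the [CLS] summary token.  The
    package provides the full surrounding pipeline: quality control
    (call rate, minor allele frequency, Hardy-Weinberg equilibrium,
    per-individual missingness), minor-allele 0/1/2 encoding with mean
    imputation, non-overlapping 6-mer tokenization, pedigree-based
    forward-validation splitting, GBLUP (VanRaden genomic relationship
    matrix with REML variance components) and Lasso baselines,
    attention-based region interpretation, and a synthetic population
    simulator with LD-block genotypes, multi-generation pedigrees and
    traits of controllable additive, dominance and epistatic architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
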