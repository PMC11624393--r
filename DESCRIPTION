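Package: sirefert
Title: Genomic Prediction of Sire Fertility with Reliability-Weighted
    Kernel Regression and Recessive Major Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Genomic prediction of dairy bull fertility from dense SNP
    genotypes. Provides quality control of SNP panels (minor allele
    frequency, call-rate and monomorphism filters), construction of the
    additive genomic relationship matrix from centered and standardized
    genotypes, a Bayesian kernel (RKHS/GBLUP-equivalent) regression fitted
    by Gibbs sampling with record reliabilities as heteroscedastic
    residual weights and recessive-homozygote indicators as fixed effects,
    repeated k-fold cross-validation scored by predictive correlation and
    mean squared error of prediction, a single-marker recessive-effect
    genome scan, a synthetic genotype/phenotype generator with planted
    recessive loci for end-to-end testing, and readers/writers for PLINK
    bed/bim/fam and additive-dosage text formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
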