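Package: prsfs
Title: Cross-Validated Comparison of SNP Feature Selection and Polygenic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A leakage-free benchmarking pipeline for case/control disease
    prediction from genotype data. Provides a synthetic genotype-phenotype
    generator (block linkage disequilibrium, Balding-Nichols population
    structure, liability-threshold phenotypes with planted causal variants,
    correlated clinical risk factors), variant- and sample-level quality
    control (minor allele frequency, missingness, minor allele count,
    Hardy-Weinberg exact test, windowed LD pruning, KING-robust kinship
    filtering), per-fold association scans (covariate-adjusted logistic
    regression, Fisher's allelic exact test, genotype principal components,
    variance-inflation screening), three SNP feature-selection strategies
    (univariate ranking, minimum-redundancy maximum-relevance, random-forest
    importance), three polygenic-score constructions (clumping+thresholding,
    L1-penalised summary-statistic regression, infinitesimal-prior
    shrinkage), and a stratified cross-validation harness with AUC
    evaluation and feature-selection stability and consensus analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    ranger,
    e1071,
    vcfR,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
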