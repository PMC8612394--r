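Package: episurv
Title: SNP-SNP Interaction Scans and Interaction Polygenic Risk Scores for
    Dichotomous Survival Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing gene-gene (epistatic) contributions to
    case-control survival traits such as survival to age 85+. Implements
    per-pair logistic regression with an additive-by-additive interaction
    term and observed covariates, candidate cross-gene and genome-wide
    fixed-SNP scan designs, genotype quality control with two-protocol
    union retention (minor allele frequency, call rate, exact
    Hardy-Weinberg test, per-individual missingness, heterozygosity and
    ancestry outliers), LD-based clumping of correlated SNP pairs to
    independent representatives with Bonferroni correction, and
    construction and evaluation of SNP-specific Interaction Polygenic
    Risk Scores (SIPRS) over a P-value threshold sweep (Nagelkerke
    pseudo-R2, likelihood-ratio P, ROC AUC with DeLong confidence
    interval). A calibrated synthetic genotype/covariate/trait generator
    with latent-Gaussian LD blocks makes every stage testable without
    access to restricted cohort data. Reads and writes PLINK bed/bim/fam.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pROC,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
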