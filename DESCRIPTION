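Package: lsimpute
Title: Trait Imputation from Multi-Ancestry GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Imputes individual-level trait values (quantitative or binary
    genetic risk) from genotypes and genome-wide association study (GWAS)
    summary statistics by least-squares inversion of the marginal-effect
    equations (LS-Imputation), and extends the approach to two ancestries:
    a closed-form omega-weighted blend of two summary-statistic sets, and a
    transfer-learning variant that refines an auxiliary-ancestry imputation
    by stochastic gradient descent with validation-based early stopping.
    Includes PLINK-1 binary genotype input/output, summary-statistic allele
    harmonization, SNP quality control (minor allele frequency, missingness,
    Hardy-Weinberg exact test, linkage-disequilibrium pruning), marginal GWAS
    on imputed traits, logistic-to-linear effect-size conversion, evaluation
    (Pearson correlation, ROC/AUC, DeLong's paired test), and a two-ancestry
    cohort simulator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
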