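Package: wipgwas
Title: Weighted Imputed Phenotypes for Case-Control Genetic Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Case-control genetic association testing that incorporates
    subjects with intermediate or missing disease status. Disease status
    is imputed from endophenotype-based prediction models selected by
    nested cross-validation, each imputed label is weighted by its
    estimated affection probability, and SNP association is tested with
    weighted generalized estimating equations (weighted logistic
    quasi-score with Wald and generalized score tests). Includes a
    misclassification bias correction of effect estimates based on a
    mediation decomposition of SNP effects, a simulation harness for
    empirical type-I error and power studies under a mediated SNP-effect
    disease model, and genome scan plumbing for PLINK and VCF genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    jsonlite,
    pROC,
    ranger,
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
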