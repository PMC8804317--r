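Package: snvpath
Title: Pathogenicity Classification of Cancer Somatic SNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for supervised classification of the
    pathogenic status of cancer somatic single-nucleotide variants (SNVs).
    Builds labeled gold standards from somatic variant catalogs using a
    bi-dimensional recurrence threshold (carrier frequency and number of
    cancer types) for positives and a population-frequency rule for
    negatives; assembles a four-group genomic feature matrix (structural
    and genomic context, epigenetic, genomic distance, conservation);
    fills missing values by chained-equation imputation; trains
    Lasso-logistic and RBF-kernel SVM classifiers with stratified
    cross-validation, ROC/AUC evaluation, and operating-threshold
    selection at a target true-positive rate; and applies trained models
    to patient cohorts with recurrent-variant selection, gene mutation
    status, and age-stratified Kaplan-Meier/log-rank survival screens.
    Includes seeded synthetic-data generators so the full pipeline is
    testable without access to licensed variant databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
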