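Package: pigsnp
Title: Discovery and Evaluation of SNP Panels for Ordinal Pigmentation Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for discovering small SNP panels that predict ordinal eye
    and hair colour in structured populations. Provides a seeded synthetic cohort
    generator (Balding-Nichols regional allele-frequency divergence, LD blocks,
    liability-threshold ordinal phenotypes), VCF/phenotype ingestion with variant
    and sample quality control, additive genotype encoding, three per-SNP
    association scorers (univariate F test, k-nearest-neighbour mutual
    information, lasso regularization path), rule-based 0-3 score aggregation
    across regional and pooled datasets with total-score ranking, and a linear
    classifier with per-class one-vs-rest ROC evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
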