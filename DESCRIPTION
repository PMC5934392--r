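Package: mpsubtype
Title: Mesenchymal-Phenotype Subtyping of Gastric Cancer Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of a mesenchymal-phenotype (MP) versus
    epithelial-phenotype (EP) dichotomy in bulk gastric-cancer expression
    cohorts. Implements variation filtering and quantile normalization,
    unsupervised two-cluster subtype discovery, two-list t-test signature
    derivation with a fold-change cutoff, a Bayesian compound covariate
    predictor with leave-one-out cross-validation and cross-classifier
    concordance, Kaplan-Meier/log-rank/Cox survival analysis including a
    subtype-by-chemotherapy interaction test, two-reference tumor-fraction
    deconvolution with stromal-content adjustment of expression, cross-cohort
    conserved-gene selection, methylation-expression correlation, and
    hypermutation classification. Ships a multi-cohort synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    limma,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
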