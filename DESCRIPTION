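Package: multilevelPLS
Title: Multilevel Sparse Partial Least Squares for Repeated-Measures Omics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance decomposition and sparse latent-variable modelling for
    repeated-measures (cross-over) omics experiments. Splits an expression
    matrix into offset, between-subject and within-subject parts (one- or
    two-factor designs), fits sparse PLS discriminant analysis on the
    within-subject matrix with L1-induced variable selection, integrates two
    matched assays with mode-A sparse PLS, tunes the number of selected
    variables by leave-one-subject-out cross-validation or in-sample
    correlation criteria, and provides a mixed-model simulator with correlated
    gene clusters for benchmarking the multilevel approach against the
    classical one.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), mixOmics, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
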