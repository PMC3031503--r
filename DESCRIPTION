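Package: gmatreg
Title: Bilinear Regression of Gene Expression on Promoter Motifs and
    Transcription-Factor Expression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers putative associations between promoter motifs and
    transcription factors (TFs) from expression data with the bilinear
    (growth-curve, GMANOVA-type) model G = M A T + E, where G is a gene
    by experiment expression matrix, M a gene by motif count matrix, T a
    TF by experiment expression matrix and A the unknown motif by TF
    coefficient matrix. Provides minimum-norm and centered least squares,
    ridge, iterative soft-thresholding sparse regression with a
    regularization path, and a correlation-based estimator; permutation
    z-scores, an overall F-test, pair ranking and split-set stability
    with a hypergeometric overlap test; promoter k-mer and GO-annotation
    matrix builders; and a seeded simulation benchmark that scores
    estimators by coefficient-recovery ROC AUC. Includes a command-line
    interface for reproducible pipeline runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    glmnet,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneRegulation, Transcription, MotifDiscovery, Regression,
    GeneExpression, Software
RoxygenNote: 7.3.3
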