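Package: evpanel
Title: Extracellular Vesicle Proteomic Biomarker Panel Discovery with
    Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for targeted proteomics (proximity extension
    assay) biomarker discovery from extracellular vesicle preparations.
    Computes Normalized Protein Expression (NPX) from Ct-level readouts,
    applies limit-of-detection and missingness filters, runs differential
    expression with a normality gate and Benjamini-Hochberg correction,
    single-marker ROC analysis with Youden's J, PCA and PLS-DA projections
    with VIP scoring, and a Monte-Carlo cross-validation stability loop
    combining three feature selectors (shadow-feature random forest,
    elastic net, PLS-DA/VIP) with a ridge-penalized logistic classifier
    (1-SE penalty rule) and pooled out-of-fold AUC, deriving a consensus
    biomarker panel. Includes a treatment-response module correlating
    within-patient NPX change with percent change in tumor burden, and a
    synthetic-cohort generator with planted signal for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    ranger,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    nortest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
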