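Package: respanel
Title: Responsive Cell Types and Sparse Gene Panels for Patient-Level
    Classification from Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies the cell population most responsive to a binary
    perturbation (disease, treatment) in patient-annotated single-cell
    RNA-seq data, selects a minimal discriminative gene panel from that
    population by support vector machine recursive feature elimination
    with patient-grouped cross-validation and automatic elbow detection,
    and classifies held-out patients by aggregating per-cell ensemble
    prediction probabilities into a per-patient AUC score with a
    bootstrap significance test. Includes a seeded negative-binomial
    simulator with per-patient random effects so every stage has a
    ground-truth recovery test, and readers/writers for h5ad, 10x MTX
    and CSV dialects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    ranger,
    e1071,
    glmnet,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
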