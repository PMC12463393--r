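Package: hypoScreen
Title: Supervised Neuron Subtyping, Opposing Gene Signatures and
    Mendelian Randomization Screens for Hypothalamic Aging Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting aging and endocrine-intervention effects
    in hypothalamus single-nucleus RNA-seq data across three sample groups
    (young, old, old-treated). Implements per-cell gene-set fraction
    scoring, supervised neuron subtyping by neuropeptide/receptor
    expression, quartile-partition derivation of opposing up-signatures,
    Wilcoxon/auROC pathway ranking, subsampled classifier-AUC cell
    perturbation prioritization, rank-intersection screens,
    over-representation analysis, and bidirectional two-sample Mendelian
    randomization with five estimators and concordance screening. A
    synthetic-data module generates expression datasets and paired GWAS
    summary statistics with planted, recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    fgsea,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
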