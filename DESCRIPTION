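Package: PanelBurden
Title: Data-Driven Targeted Gene Panels for Estimating Exome-Wide
    Mutation Burden
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design of targeted gene panels for cost-effective estimation of
    exome-wide mutation-count biomarkers such as tumour mutation burden (TMB)
    and tumour indel burden (TIB). Mutation counts per sample, gene and
    variant group are modelled as independent Poisson variables with a log
    link decomposing the rate into a per-sample background mutation rate,
    a gene-length offset, and L1-penalized gene and gene-by-variant-type
    effects, tuned by cell-wise ten-fold cross-validation. Biomarker
    estimators are weighted linear combinations of panel counts, selected by
    a length-weighted group lasso with a panel-size budget, refitted on the
    selected support, optionally augmented around a mandatory gene set, and
    accompanied by conservative Markov-bound prediction intervals. Includes
    count-rescaling and linear-regression baselines, regression and
    classification metrics (R-squared, precision-recall, ROC), a synthetic
    cohort generator drawn from the generative model, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    MASS,
    optparse,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, StatisticalMethod, SomaticMutation, Sequencing,
    TargetedResequencing, Regression
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PanelBurden-package.R'
    'utils.R'
    'mutation-data.R'
    'generative-model.R'
    'cli.R'
    'panel-selection.R'
    'evaluation.R'
    'prediction.R'
    'synthetic-data.R'
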