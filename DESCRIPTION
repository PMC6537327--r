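Package: coexBench
Title: Benchmarking Batch-Effect Correction by Recovery of Known Gene-Gene
    Associations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates batch-effect correction methods for bulk gene-expression
    data by how well the adjusted matrix recovers a-priori true gene-gene
    associations and rejects false ones. A confidence-scored interaction
    network is thresholded into a calibrated gold standard of true and false
    gene pairs; every pair is scored in the (adjusted) expression matrix by
    Spearman correlation with t-approximation p-values, Benjamini-Hochberg
    correction and a -log10 score; methods are compared by ROC curves and AUC
    against the gold-standard labels. Ships the residualization-based
    corrections it contrasts (known-covariate regression, hidden-factor and
    principal-component removal, iterative empirical-Bayes location/scale
    batch adjustment) and a synthetic-data generator with planted
    co-expression modules and batch artefacts for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: BatchEffect, QualityControl, Normalization, NetworkInference,
    GeneExpression, Software
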