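Package: relabeler
Title: Post Hoc Correction of Cell Type Labels in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies and corrects mislabelled cells in an annotated
    single-cell RNA-seq dataset. Starting from an expression matrix and an
    initial per-cell type annotation, the pipeline reduces the data to
    principal components, iteratively estimates each cell's mislabelling
    probability with adaptive weighted resampling (AdaSampling) around a
    probabilistic base classifier (Platt-scaled RBF support vector machine
    or random forest), and reclassifies cells by ensemble-averaged class
    probabilities. Includes a group-structured negative-binomial count
    simulator with cyclic label-flip noise injection and the evaluation
    metrics (per-class mean accuracy and pair-count adjusted Rand index)
    used to benchmark label correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    randomForest,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
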