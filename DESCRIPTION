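Package: lrnet
Title: Ligand-Receptor Interactome Signatures of Immunotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-sample ligand-receptor interaction inferences from
    tumor single-cell data into interaction-frequency statistics per directed
    cell-type pair, multivariate interaction signatures separating patient
    groups (stability LASSO feature selection, two-stage orthogonalized
    PLS-DA with VIP scores, permutation-based empirical p-values, and a
    Pearson co-correlate network), and a survival stratification from
    ligand-receptor expression scores. Includes NRMSE-guided selection of a
    missingness threshold and imputer (random forest, k-nearest neighbours,
    or column mean), and a synthetic-data generator with planted ground
    truth so every stage can be validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    randomForest,
    survival,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
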