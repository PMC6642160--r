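Package: rccpath
Title: Whole-Slide Tiling, DAG-SVM Subtype Classification and Morphometric
    Survival Stratification for Renal Cell Carcinoma Histopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale implementation of a renal cell carcinoma (RCC)
    histopathology analysis pipeline. Whole-slide images are tiled into
    overlapping patches with intensity-based background removal; a pluggable
    patch scorer provides class probabilities and penultimate-layer
    embeddings; a decision-DAG support vector machine (DAG-SVM) performs
    multiclass subtype calls from the embeddings, with class-imbalance
    remedies (minority augmentation, inverse-frequency resampling weights);
    per-slide tumor-probability heatmaps are thresholded and cleaned into
    tumor masks; region and nuclei morphometry is aggregated to patient
    level; and lasso-regularized Cox models inside a two-level
    cross-validation stratify patients into low/high risk groups with
    log-rank, Kaplan-Meier and multivariate Cox reporting. A synthetic-data
    module generates tissue-like slides, nuclei scenes and survival cohorts
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    glmnet,
    grDevices,
    jsonlite,
    nnet,
    png,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
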