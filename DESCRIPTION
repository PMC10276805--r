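Package: cytofuse
Title: Two-Level Classification of Thyroid Cytology Cell Clusters from
    Correlative Color and Refractive-Index Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for machine-learning classification of thyroid
    fine-needle aspiration biopsy cell clusters imaged with two
    registered modalities: Papanicolaou-stained color brightfield and a
    2D Z-projection of the refractive-index (RI) tomogram. Implements
    overlapping 256x256 patch tiling with a mean-color inclusion filter,
    grouped and stratified dataset splitting, a per-modality patch-level
    convolutional classifier, per-cluster malignancy prediction maps
    with heatmap feature extraction, tree-ensemble cluster
    classification (color-only, RI-only and combined), confusion-matrix
    performance reporting, and model-explanation analyses (Grad-CAM
    saliency, Brenner-gradient detail statistics, prediction-score
    binning and t-SNE of patch embeddings). A synthetic correlative
    cytology generator with ground-truth nuclear masks provides seeded,
    reproducible study conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    cluster,
    e1071,
    jsonlite,
    nnet,
    png,
    randomForest,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
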