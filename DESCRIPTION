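Package: mvholdout
Title: Stability-Optimized Multiple-Holdout Framework for Sparse PLS and
    Regularized Kernel CCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates hidden dimensions relating two high-dimensional data
    views (for example voxelwise brain measures and item-level behavioral
    variables) with regularized cross-modality latent-variable models: sparse
    partial least squares (SPLS) via alternating soft-thresholded updates, and
    regularized kernel canonical correlation analysis (KCCA) whose
    regularization interpolates between correlation and covariance
    maximization. Models are embedded in a nested multiple-holdout resampling
    scheme that selects hyperparameters by a joint stability and
    generalizability criterion, tests out-of-sample generalization of each
    latent effect by permutation on held-out data, and extracts successive
    effects by matrix deflation. Includes a synthetic paired-data generator
    with known sparse latent structure, recovery metrics, tidy() and glance()
    methods, and ggplot2-based plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
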