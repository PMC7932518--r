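Package: phenovoxel
Title: Segmentation-Free Phenotypic Profiling of 3D High-Content Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multichannel 3D fluorescence microscopy stacks into
    data-driven phenotypic feature vectors without cell segmentation, using a
    pixel / supervoxel / megavoxel category hierarchy learned by k-means on a
    small training set. Includes training-set intensity rescaling, maximum
    correlation thresholding, affinity-propagation clustering with automated
    preference estimation by knee-point detection, random-forest phenotype
    classification with cross-validated Cohen's kappa, mutual information
    between groupings, organoid localization and cropping in large sparse
    stacks (focus stacking, contour segmentation, z-range selection, 2D
    morphology and hollowness), low-dimensional feature-space embeddings, and
    fully programmatic synthetic fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    EBImage,
    randomForest,
    mclust,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
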