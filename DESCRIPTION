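Package: vectex
Title: Vector Texture Features from Derivative Domains of 3D Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts vector texture features from volumetric images for
    lesion classification. First-order (Sobel gradient) and second-order
    (Deriche Hessian eigenvalue) derivative fields are converted to
    spherical coordinates, quantized into vector texture images (VTIs),
    and summarised by vector co-occurrence matrices (VCMs) along the 13
    canonical 3D directions. Each VCM yields 28 Haralick-style texture
    measures, giving a 364-entry feature vector per lesion, which feeds a
    random-forest classifier with GINI-importance forward feature
    selection under stratified twofold and leave-one-out cross-validation.
    Includes a seedable phantom generator producing CT-like lesion
    cohorts with class-dependent texture statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
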