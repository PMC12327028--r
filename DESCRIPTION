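Package: octavess
Title: Three-Dimensional OCT Angiography Processing and Vessel Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A processing and analysis toolkit for three-dimensional optical
    coherence tomography angiography (OCTA) of skin. Provides seeded synthetic
    phantoms of layered speckled tissue and tubular vascular networks; a
    compact U-Net for B-scan segmentation of epidermis and dermis with
    CLAHE preprocessing, boundary-surface extraction and thickness maps; a
    3D curvelet tight frame with scale-dependent hard thresholding and
    direction-selective stripe suppression; multi-radius optimally-oriented-
    flux (OOF) tubular enhancement; binarization, connected-component
    filtering and topology-preserving 3D skeletonization; and multiparametric
    vessel quantification (vessel area, skeleton length, and their dermis-
    restricted densities, in 3D and on en face maximum-intensity
    projections) together with a longitudinal average-rate-of-change
    statistic, orchestrated by a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    tiff,
    RNifti,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
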