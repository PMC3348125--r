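Package: nuclei3d
Title: Direct Extraction of Nuclei Centroids from 3D Fluorescence
    Microscopy Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects nuclei centroids in three-dimensional fluorescence
    microscopy volumes without segmentation.  Implements Gaussian and
    median pre-filtering with resolution-aware kernel sizes, cubic
    z-interpolation to near-isotropic voxels, multiscale separable cube
    filtering for local enhancement, characteristic-ratio local-maxima
    detection, intensity-profile shape refinement, and distance-based
    merging of fragmented detections, together with matching-based
    detection metrics (sensitivity, precision, RMSE, specificity) and a
    synthetic embryo-volume generator that emits known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
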