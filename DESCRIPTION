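Package: rpemorph
Title: 3D Morphometry of Segmented Retinal Pigment Epithelium Volume-EM Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative 3D morphometry for serial block face scanning
    electron microscopy (SBF-SEM) label volumes of the outer retina.
    Reads anisotropic multi-page TIFF label stacks with an external JSON
    label table, computes per-cell per-compartment volumes and voxel-face
    surface areas, estimates shared contact area between adjacent cells
    with a slice-wise dilate-and-intersect algorithm (plus an independent
    voxel-face oracle and a cell adjacency graph), counts photoreceptor
    outer segments supported by each cell, quantifies mitochondria by
    3D connected components, and measures microvillus length and tilt
    angle, epithelial height and Bruch's membrane thickness under a
    slice-sampling protocol. A synthetic outer-retina phantom generator
    with analytically known ground truth validates every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    igraph,
    data.table,
    EBImage,
    generics,
    readr,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
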