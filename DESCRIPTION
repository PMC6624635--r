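Package: glandseg
Title: Blind Color Decomposition and Gland Segmentation for
    Picrosirius Red-Hematoxylin Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments prostate glands in Picrosirius red-hematoxylin
    (PSR-Htx) stained brightfield tissue images. Implements blind color
    decomposition of RGB tiles into stromal and epithelial stain density
    maps (Beer-Lambert optical density, chromaticity-triangle mapping,
    expectation-maximization of a Gaussian mixture, non-negative linear
    unmixing), a morphology-driven gland segmentation (grayscale opening,
    gradient-maximization thresholding, adaptive elliptical erosion for
    seed extraction, marker-controlled watershed, nucleus-presence
    filtering), stain-protocol quality metrics (Mahalanobis cluster
    separation, Calinski-Harabasz index, mixture weights), a forward-model
    generator of synthetic PSR-Htx-like tiles with per-pixel ground truth,
    and object-level evaluation of segmentations (correct / over- /
    under-segmentation taxonomy with summary tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
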