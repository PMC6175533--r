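Package: vesisort
Title: Segmentation and Classification of Synaptic Vesicles in Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to segment synaptic vesicles in 3D electron tomograms,
    extract per-vesicle image features (inner radius, mean gray value,
    central-slice gray-value standard deviation, distance to the active
    zone), classify clear-core versus dense-core vesicles with a shipped
    standardized linear classifier or retrainable alternatives (linear and
    RBF support vector machines, random forest, k-nearest neighbours), and
    summarise vesicle-pool statistics. Includes a synthetic phantom
    generator with known ground truth so the whole pipeline can be
    exercised and validated without external image data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    e1071,
    randomForest,
    class,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
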