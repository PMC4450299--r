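Package: lungfield
Title: Lung-Field Extraction and Juxtapleural Boundary Correction for Thoracic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts lung fields from 2D thoracic CT slices and slice stacks
    and repairs the segmentation boundary around juxtapleural nodules. The
    segmentation minimizes a convexified global+local region energy (Chan-Vese
    plus local binary fitting) weighted by a structure-tensor edge indicator
    and solved by split Bregman iteration. Post-processing removes the central
    airway by an osseous-neighborhood test with previous-slice propagation,
    detects defective boundary blocks by box-counting fractal dimension, and
    re-includes excluded nodules with a region-coded geometric active contour.
    A built-in phantom generator produces CT-like slices with ground-truth
    masks so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    RNifti,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
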