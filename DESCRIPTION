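Package: mptrack
Title: Multi-Parametric Cell Tracking for Fluorescence Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation, parameterization and multi-parametric tracking of
    fluorescently labeled cells in time-lapse microscopy, with migration and
    growth statistics for chemotaxis assays. Implements a Hessian-eigenmap
    segmentation chain (background subtraction, saturating intensity
    adjustment, block downsampling, blob detection, adaptive peak splitting,
    marker-seeded region growing and full-resolution boundary refinement),
    equivalent-ellipse cell descriptors, weighted feature-deviation
    frame-to-frame linking, and per-track and per-condition migration
    statistics (velocities, Euclidean and accumulated distance, forward
    migration index, directness, normalized cell counts). Includes a
    synthetic time-lapse simulator with ground-truth tracks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    tools,
    clue,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
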