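Package: airwaymorph
Title: Upper-Airway Morphometry from 3D Cephalometric Landmarks with
    Symbolic-Regression Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for craniofacial upper-airway morphometry from 3D
    anatomical landmarks and voxelized airway segmentations. Reorients
    subjects to the Frankfort horizontal and midsagittal planes, computes a
    standard panel of 6 cephalometric angles and 19 distances, extracts
    airway volume and the minimal axial cross-sectional area (with its
    anteroposterior and lateral extents) from binary voxel grids, and models
    airway size with a genetic-programming symbolic-regression engine that
    reports normalized fitness-weighted variable importance and signed
    sensitivity magnitudes. Classical statistics (descriptives, two-way
    mixed-effects intraclass correlation, Kendall tau-b correlation
    matrices, principal component analysis) and a synthetic-cohort
    generator with planted anatomical effect structure are included so the
    whole pipeline is testable without clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    RNifti,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
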