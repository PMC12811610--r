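Package: hipposheet
Title: Geometry-Based Unfolding, Thickness and Shape Analysis of the
    Hippocampal Body
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a sheet representation and intrinsic coordinate system
    of the hippocampal body from subfield segmentations. Starting from a
    labeled volume (NIfTI or MGZ; FreeSurfer- or ASHS-style labels), the
    package extracts a smoothed surface and conforming tetrahedral mesh,
    locates the medial and lateral boundary curves via the first
    eigenfunction of a curvature-aware anisotropic Laplace-Beltrami
    operator, solves three volumetric Laplace problems to obtain a harmonic
    map to a degenerated unit cube, and derives a mid-surface grid with
    streamline thickness, mean curvature, and further shape summaries
    (extents, circumference, interior/exterior ratio, surface area, shape
    index, slice areas). Group analysis tools provide curvature-based
    inter-subject alignment, grid-point-wise linear models with joint
    false-discovery-rate control across hemispheres, and incremental
    logistic classification. A synthetic phantom generator with analytic
    ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    RNifti,
    igraph,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
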