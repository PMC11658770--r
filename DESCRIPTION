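Package: tigon
Title: Tension Inference and Tension-Isogonal Decomposition for Epithelial Cell Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Force-balance analysis of planar, tracked epithelial cell meshes.
    Infers relative cortical tensions from the angles at tri-cellular vertices
    (tension triangles and kites), decomposes cell-array deformation into a
    tension-driven part and an isogonal (angle-preserving) part, computes the
    geometric T1 threshold from the Voronoi reference state of the tension
    triangulation, detects and classifies cell neighbor exchanges (T1 events)
    in tracked time series, quantifies local tension-configuration order
    (bridge/cable motifs), and simulates a minimal periodic cell-quartet model
    of active and passive intercalation driven by positive tension feedback.
    Includes a synthetic-data generator producing meshes and tracked sequences
    with exact ground-truth tensions, isogonal strain and programmed T1 events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
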