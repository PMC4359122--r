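Package: bodyhull
Title: Body Segment Inertial Parameters from 3D Surface Scans via Convex Hulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes subject-specific body segment parameters (volume, mass,
    centre of mass and full inertia tensor) from scaled, landmark-annotated 3D
    surface point clouds of standing subjects. Point clouds are cut into
    anatomical segments by landmark-defined planes, each segment is convex
    hulled (optionally after longitudinal subdivision to reduce hull
    overestimation of concave segments), and exact polyhedral mass-property
    integration under segment-density assumptions yields per-segment inertial
    properties.  A pro-rata density scaling factor closes the total to the
    measured subject mass.  Includes a synthetic humanoid generator with
    closed-form ground truth for validation, Monte-Carlo and voxel reference
    integrators, ASCII PLY/OBJ/XYZ readers and writers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
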