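Package: smlmkit
Title: Headless Analysis Toolkit for Single-Molecule Localization Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-molecule localization microscopy (SMLM)
    point clouds and single-particle-tracking trajectories without a graphical
    front end: delimiter-agnostic localization-table I/O with JSON analysis
    records, 3D geometric selection (sphere, convex hull, clipping plane,
    column threshold) and measurement tools, local density estimation,
    blinking-localization merging, mean-squared-displacement and
    maximum-likelihood diffusion/drift estimation with localization-noise
    correction, anomalous-exponent fitting, a 3D diffusivity/force mapping
    pipeline (k-means tessellation, per-region inference, colored convex-hull
    region meshes exported as PLY/OBJ), trajectory and blinking simulators for
    validation, and timed camera-waypoint interpolation for fly-through export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
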