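Package: phenokit
Title: Classical Image-Analysis Pipelines for Smartphone Plant Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit of classically computed plant-phenotyping
    pipelines: seed morphometrics with coin-based scale calibration, tomato
    fruit measurement via bounded-HSV segmentation, wheat spikelet counting and
    angle analysis (convex-hull gated watershed splitting, RANSAC axis fits,
    polynomial ear axis, Zhang-Suen skeletonization), canopy shape and green
    ratio, maize kernel row features via PCA alignment and 1-D K-means, flag
    leaf angle from keypoints, and wheat head density with rectangular-marker
    perspective rectification. Includes a synthetic-scene generator with exact
    ground truth so every stage is testable against known generative
    parameters, plus an R-squared soundness harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jsonlite,
    cluster,
    stats,
    grDevices,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
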