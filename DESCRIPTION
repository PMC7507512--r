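Package: fieldmosaic
Title: Mosaicking of Aerial Crop-Field Video by Grouped Homography Chaining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds seamless two-dimensional mosaics from aerial video of
    approximately planar crop fields using only the imagery: shot detection by
    clustering cumulative-histogram difference energies, adaptive feature
    registration with descriptor escalation and RANSAC inlier filtering,
    grouped homography chaining to a base frame, canvas estimation, and
    pixel-fill blending, together with structural-similarity quality metrics
    and a synthetic-flight simulator that provides ground-truth homographies
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
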