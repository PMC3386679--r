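Package: SurfaceDP
Title: Optimal-Surface Dynamic Programming for Boundary Detection in
    Image Sequences
Version: 0.99.0
Authors@R: person(given = "Package", family = "Author",
    email = "author@example.com", role = c("aut", "cre"))
Description: Detects closed boundaries of round, bright objects (such as
    the cross-sectional lumen of an artery) through an image sequence by
    extracting a minimal-cost surface from a volumetric feature matrix
    with a two-pass three-dimensional expansion of dynamic programming.
    Images are resampled to polar coordinates around a user-supplied
    centre so that a closed contour becomes a left-to-right path; radial
    image gradients provide the boundary evidence, and a smoothness
    constraint links contours of neighbouring frames so that the
    detection survives frames with vague or absent boundary evidence.
    Includes a disc-phantom simulator with noise calibrated to a target
    signal-to-noise ratio, relative unsigned area error and Bland-Altman
    agreement statistics, a parameter-sweep harness, and readers/writers
    for TIFF and PNG stacks together with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
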