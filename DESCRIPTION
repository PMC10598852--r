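Package: teapick
Title: Side-View Tea Shoot Picking-Point Localization and Harvest Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-dimensional, side-view localization of tea shoot
    picking points and for planning the vertical motion of a continuously
    advancing mechanical picker. Provides a synthetic scene generator with
    exact world-coordinate ground truth for side-view tea rows, binary image
    thinning by the two-subiteration fast parallel (Zhang-Suen) algorithm,
    skeleton-based detection of the bud-leaf intersection, stem growth-curve
    fitting with a fixed 4 mm picking offset, linear pixel-to-world camera
    calibration, S-curve (logistic) velocity profile planning for the picker,
    and a harvest simulator that scores strip-clamping and picking success
    the way a field trial is scored.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
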