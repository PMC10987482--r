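Package: refplane
Title: Reference Effective Focal Plane Estimation from Brightfield Bead Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking the Z axis of a brightfield microscope with
    control microsphere beads. Detects beads in field-of-view images, extracts
    background-normalized steepest-slope and center-intensity features from
    cubic smoothing splines fit to each bead's radial intensity profile,
    pools feature-versus-Z sweep curves across exposures and fields of view to
    define a reference effective focal plane (REFP), and trains an ensemble of
    small convolutional regression networks that predict the signed distance of
    a single acquisition from the REFP. Includes a synthetic bead-field
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
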