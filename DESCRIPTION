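Package: eggfit
Title: Egg Volume Estimation from Partial Range-Camera Point Clouds
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates bird-egg volume from a single range-camera view of
    roughly half the eggshell.  Implicit three-dimensional egg-shape models
    (two shape parameters plus pose and optional shear-distortion terms) are
    fitted to the point cloud by Gauss-Helmert least squares; the volume and
    its standard deviation then follow in closed form from the shape
    parameters and their covariance.  Includes intensity-based eggshell
    segmentation (center window, Otsu threshold, robust surface filter),
    automatic initial-value computation from the raw half-shell cloud, a
    synthetic range-camera scene generator with ground truth, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
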