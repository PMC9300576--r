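Package: nsafit
Title: Automatic Measurement of the Femoral Neck-Shaft Angle from Labeled Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the femoral neck-shaft angle (NSA) from region-labeled
    point clouds of single femurs by two automatic routes: direct 3D axis
    fitting (least-squares head-sphere centre, neck centroid, shaft slab
    centroids) and 2D measurement on a simulated anteroposterior projection
    plane (point-to-plane projection, RANSAC circle fit of the projected
    head). Includes a parametric synthetic femur generator with analytically
    known ground truth, segmentation and angle-agreement evaluation metrics
    (Dice, mean IoU, error/accuracy, two-sample t-test, cross-entropy), and
    readers/writers for labeled PLY, XYZ and CSV point clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
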