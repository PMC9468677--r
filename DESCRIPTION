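Package: tensiomag
Title: Magnetic Force Tensiometry of Multicellular Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the surface tension of multicellular spheroids from
    side-view images of aggregates flattened by a magnetic body force.
    Integrates the axisymmetric Young-Laplace shape equation with a uniform
    body force, fits the apex curvature and capillary constant to the
    observed height, width and volume, and converts the capillary constant
    to a surface tension using the magnetic calibration (moment per unit
    volume and field gradient).  Also quantifies the companion assays of a
    typical epithelial-mesenchymal-transition study: AFM cell-cell
    detachment force from retraction curves, scratch-wound coverage over
    time, and transwell invasion indices, with two-sided Mann-Whitney
    comparisons and notched-boxplot summaries.  A seed-deterministic
    synthetic-data generator produces every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    signal,
    pracma,
    withr,
    generics,
    Rcpp,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
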