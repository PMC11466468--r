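Package: tomolot
Title: Leaf Open Time Reconstruction and Validation for Tomotherapy Binary MLCs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the leaf open times (LOTs) executed by the 64-leaf
    pneumatic binary multileaf collimator of a tomotherapy unit from two
    independent telemetry streams: the 640-channel megavoltage exit-detector
    trace (via arc correction, leaf-to-channel interpolation, offset
    subtraction, Richardson-Lucy deconvolution and width-at-threshold
    measurement) and the per-leaf optical position-sensor event stream (via
    three-state sequence segmentation and a threshold-weighted transition
    formula). Both methods are calibrated against an ionization-chamber
    charge-ratio ground truth and validated with paired t-tests, Pearson
    correlation and linear fits. A parametric leaf-motion simulator generates
    all three telemetry streams with known ground truth, so the whole
    calibration and validation workflow is exercisable without machine data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
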