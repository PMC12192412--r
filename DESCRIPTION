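Package: iristrack
Title: Visible-Light Iris Tracking with Hough Circles, Active Contours and
    Masked Template Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking the iris centre in visible-light eye videos
    recorded with consumer cameras. Implements two trackers: CHT_ACM, which
    refines an eye region with a morphological active contour, binarises it,
    detects circles with the Circular Hough Transform and keeps the candidate
    whose interior is mostly dark; and CHT_TM, which builds an iris template
    from the first frame and localises it in later frames by masked normalised
    cross-correlation with darkest-region selection. Includes per-axis
    validation metrics (MAE, MPE, RMSE, Pearson correlation with t-based
    p-values), grouped comparison tables, a seeded synthetic eye-video
    generator with ground truth for end-to-end testing, and benchmarking and
    pipeline drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
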