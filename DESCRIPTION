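Package: orbias
Title: Slice-Wise Muscle Volumetry and Occupation-Ratio Bias Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying how single-slice occupation ratios
    misrepresent three-dimensional muscle volume in rotator-cuff disease.
    Provides voxel phantoms of spindle-shaped muscles with analytically
    known volumes, gap-aware slice-stack volume integration with
    Feret-style long/short axis measurement, Y-view occupation-ratio
    morphometry with Thomazeau staging, Ellman and Patte tear grading,
    and cohort statistics including the atrophy-overestimation ratio that
    arises from medial retraction of the myotendinous unit in
    full-thickness supraspinatus tears.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
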