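Package: nestsurvey
Title: Nest Count Surveys for Great Ape Density Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of great ape nest count surveys along line transects.
    Fits conventional distance-sampling detection functions (uniform and
    half-normal keys with cosine adjustments, AIC selection, chi-square,
    Kolmogorov-Smirnov and Cramer-von Mises goodness of fit), estimates nest
    densities by the standing-crop nest count (SCNC) method and nest-builder
    densities by the marked nest count (MNC) strip-transect method,
    back-calculates nest decay rate with delta-method error propagation,
    combines habitat-stratified estimates into area-weighted averages with
    transect-level bootstrap confidence intervals, and tests nest placement
    against landscape features (roads, rivers, settlements) with a Monte
    Carlo randomization test inside a transect buffer. A survey simulator
    with known ground truth (builder density, nest production and decay,
    distance-dependent detectability, habitat mosaic) supports design
    studies and end-to-end validation.
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
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
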