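Package: roastspec
Title: Hyperspectral Chemometrics for Coffee Roasting-Degree Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end near-infrared hyperspectral imaging workflow for
    classifying the roasting degree of coffee beans. Provides reflectance
    calibration against dark and white reference frames, region-of-interest
    mean-spectrum extraction, band trimming, deterministic Kennard-Stone
    sample partitioning, three effective-wavelength selectors (principal
    component X-loading extrema, the successive projections algorithm, and
    random frog subset search with an inner partial least squares model),
    and a multiclass least-squares support vector machine with a radial
    basis function kernel. A synthetic-scene generator emulates line-scan
    reflectance cubes of beans at seven roasting degrees so the whole
    pipeline is testable without instrument data; ENVI-style
    band-interleaved-by-line cubes can also be read and written.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
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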