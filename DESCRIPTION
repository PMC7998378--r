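Package: hypoxiq
Title: Quantitative Pipeline for Hypoxia-Induced Quiescence and
    Radioresistance Assays
Version: 0.1.0
Authors@R:
    person("hypoxiq", "developers", email = "hypoxiq@example.org",
           role = c("aut", "cre"))
Description: Analysis machinery for assays that link tumor-cell hypoxia,
    G1/G0 quiescence and radiation response: clonogenic survival-curve
    statistics with linear-quadratic fitting and extra-sum-of-squares
    F-tests, per-nucleus DNA-damage foci counting, FUCCI cell-cycle phase
    tracing with non-cycling classification, CDK2-activity reporter
    cytoplasm/nucleus ratio scoring, zonal analysis of stained spheroid
    cross-sections with H-AEC color deconvolution, and 3D FUCCI spheroid
    radial profiling with spherical shortest-distance correction. A
    synthetic-data module generates every input with known ground truth
    for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
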