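Package: spatnuc
Title: Spatial Point Pattern Analysis for Sparse 3D Nuclear Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether sparse three-dimensional point patterns of nuclear
    compartments (for example PML nuclear bodies) deviate from complete
    spatial randomness (CSR). Provides a synthetic-nucleus simulator built
    from perturbed piecewise-ellipsoid boundaries, thinning-based point
    processes with polar, central, and peripheral spatial preference,
    Monte-Carlo estimation of the empty-space (F-) function, pointwise
    envelope tests (individual, pooled-null, and aggregate-distance
    variants), the Spatial Distribution Index (SDI) with its population-level
    Kolmogorov-Smirnov uniformity test, and a power-study runner that
    evaluates all test variants over collections of simulated nuclei.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
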