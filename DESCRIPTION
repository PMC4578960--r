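Package: zonebee
Title: Zoning Protected Ecological Areas on Raster Landscapes with an
    Artificial Bee Colony Optimizer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects a fixed quota of raster cells for ecological protection
    by maximizing ecological suitability and neighborhood-density compactness
    while minimizing urban development potential, using a discrete artificial
    bee colony metaheuristic with mixed population initialization,
    replace-and-alter neighbor generation, swap local search and scout
    restarts. Includes a deterministic density-slicing baseline, a synthetic
    multi-peak Gaussian validation landscape with a known circular optimum,
    solution-quality and run-stability evaluation utilities, ESRI ASCII grid
    input/output, a weighted linear summation helper for building suitability
    layers from factor maps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
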