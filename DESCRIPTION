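Package: rootbench
Title: Benchmarks for Functional-Structural Root Water Uptake Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained implementation of desk-scale benchmark problems
    for functional-structural root architecture models of root water uptake.
    Provides van Genuchten-Mualem soil hydraulics, analytical reference
    solutions for infiltration, evaporation and single-root uptake,
    mass-conservative finite-volume Richards solvers on vertical, radially
    symmetric and structured 3D grids, a stochastic root architecture
    generator with RSML input/output, root-architecture metrics (Fitter
    indices, rooting-depth distribution index, persistence barcodes and
    bottleneck distances), a sparse xylem network solver, and the coupled
    soil-root uptake scenarios with sinusoidal transpiration and stress
    switching. Benchmark outputs are written in the prescribed plain-text,
    CSV, RSML and legacy VTK formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    xml2,
    jsonlite,
    minpack.lm,
    igraph,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
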