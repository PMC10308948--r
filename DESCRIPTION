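Package: lvcheck
Title: Testing Lotka-Volterra Adequacy for Microbial Interactions from
    Spent-Medium Assays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding when a generalized Lotka-Volterra (LV) model
    adequately represents chemically mediated interactions among bacterial
    isolates. Implements logistic growth-curve parameter estimation from
    plate-reader time series (growth rate, carrying capacity, lag time),
    quantification of pairwise interactions from growth in cell-free spent
    medium (CFSM), the growth-rate/carrying-capacity linear-consistency
    criterion for LV adequacy, two-species LV coculture simulation with
    fluorescence-based deconvolution of species densities, inference of
    interaction coefficients from coculture dynamics, and a synthetic
    plate-reader data generator for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
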