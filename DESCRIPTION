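Package: scafmech
Title: Viscoelastic, Morphometric and Transport Analysis of Conductive
    Tissue-Engineering Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for scaffold-coupled electrical stimulation
    studies of chondrogenic cells on conductive foam scaffolds: simulation
    of unconfined-compression dynamic mechanical analysis (DMA) traces from
    Prony-series viscoelastic materials, extraction of the five standard DMA
    endpoints (compressive, equilibrium and dynamic moduli, stress
    relaxation, phase shift), hysteresis-loop energy dissipation with
    exponential-decay modelling, microCT-style binary-volume morphometry
    (porosity, structure thickness, object volume/surface densities,
    Euler-characteristic connectivity density), diffusive tortuosity and
    directional percolation by a steady-state finite-volume solve, and
    effective electric-field estimation from RMS stimulation voltage,
    electrode distance and tortuosity.  Includes seeded synthetic-data
    generators (bioreactor traces, strut-network foam volumes, analytic
    phantoms) with ground truth attached, plus cohort statistics and
    report assembly.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Matrix,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
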