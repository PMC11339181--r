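Package: stentflow
Title: Virtual Flow-Diverter Deployment and Lattice-Boltzmann Aneurysm Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale in-silico workflow for braided flow-diverter treatment of
    intracranial aneurysms. Generates parametric sidewall aneurysm geometries,
    deploys a braided stent modelled as a calibrated spring network, represents the
    deployed device as a homogeneous Darcy-Forchheimer porous layer parameterized by
    measured hydrodynamic-resistance coefficients, solves incompressible pulsatile
    blood flow with a D3Q19 lattice-Boltzmann solver, and computes the aneurysmal
    mean velocity reduction (AMVR) endpoint together with study-level statistics:
    the power-law AMVR versus linear-resistance relationship, Welch group
    comparisons of device types, and threshold classification against the 35%
    AMVR surrogate endpoint.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
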