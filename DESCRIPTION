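Package: nlswei
Title: Nonlinear Shear Wave Elastography Simulation of a Compressed
    Breast Phantom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates shear wave elasticity imaging (SWEI) of a
    two-dimensional hyperelastic breast phantom containing a stiff
    circular tumor, under external quasi-static compression from 0 to 30
    percent. Implements a second-order polynomial (Mooney-Rivlin family)
    strain-energy model with tangent shear modulus at finite pre-strain,
    a plane-strain finite-element compression solver with frictionless
    platen contact, an explicit elastodynamic solver for shear wave
    propagation through the pre-strained medium, and a time-of-flight
    reconstruction pipeline (frequency-wavenumber directional filtering,
    arrival-time slope fitting, median smoothing) yielding shear modulus
    maps and tumor-to-background contrast versus compression level.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
SystemRequirements: C++17
NeedsCompilation: yes
Config/testthat/edition: 3
RoxygenNote: 7.3.3
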