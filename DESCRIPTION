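Package: nanodialyzer
Title: Transport, Adequacy and Design-Selection Models for Ultrathin-Nanomembrane Hemodialyzers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and finite-difference models of diffusive solute
    clearance in microfluidic dialyzers built on ultrathin nanoporous
    (silicon/silicon-nitride) membranes. Provides the dimensionless 1-D
    diffusion model of the blood channel with perfect-sink and
    membrane-resistance (Robin) boundary conditions, hindered-pore
    diffusivity models, steady-state dialysis adequacy predictions for
    continuous treatment, a three-step design-selection algorithm (urea
    isoline, albumin isocurve, middle-molecule maximisation),
    Crank-Nicolson and 2-D advection-diffusion numerical cross-checks,
    and back-of-envelope hydraulics (parallel-plate Poiseuille flow,
    priming volume). Ships a small solute library of uremic-toxin
    kinetics and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
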