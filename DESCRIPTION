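Package: skinpk
Title: Compartmental Modelling of Percutaneous Drug Transport and
    In Vitro-In Vivo Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing skin permeation experiments with a
    one-compartment membrane transport model under infinite- and
    finite-dose regimens, alongside the classical Fickian series
    solution. Estimates the zero-order input rate and first-order
    output rate constant from Franz diffusion cell cumulative
    permeation data by nonlinear least squares, derives permeability
    coefficients and lag-time analogues, performs non-compartmental
    analysis of plasma profiles, and couples the skin model to a
    two-compartment disposition model to predict plasma
    concentrations after transdermal dosing from parameters measured
    in vitro. Includes a synthetic-data generator emulating the
    sampling designs of rat nortriptyline permeation studies and an
    end-to-end pipeline reproducing the nortriptyline worked example.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
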