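Package: fdkin
Title: Kinetic Modelling and Global Fitting of Facilitated Dissociation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action reaction networks and closed-form rate laws for
    target-host-effector competition by mutually exclusive, conformational
    selection and induced-fit mechanisms; nonlinear least-squares fitting of
    exponential time courses, dose-response series and fluorescence
    polarization isotherms; a multi-cycle surface plasmon resonance model
    with accumulation of effector-unresponsive host, globally fitted across
    effector concentrations with effective-rate extraction; and synthetic
    assay generators with known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
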