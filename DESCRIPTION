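Package: aortaBC
Title: Inlet Boundary-Condition Comparison for Image-Based Aortic Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how the choice of inlet velocity boundary
    condition (flat, through-plane, or full three-dimensional profiles derived
    from phase-contrast MRI) affects computed thoracic-aorta hemodynamics.
    Generates analytic, time-periodic tube flow fields (Poiseuille, Womersley,
    swirling and eccentric valve-jet flows) and emulated PC-MRI plane
    acquisitions with velocity encoding and aliasing; maps acquired velocity
    maps onto an inlet patch through a rigid coordinate transfer fitted from
    reference points; drives a three-element Windkessel outlet model; and
    computes wall shear stress, time-averaged WSS, oscillatory shear index,
    spatiotemporal WSS maps, helicity density, local normalized helicity, and
    the helicity flow index from Lagrangian particle traces. An end-to-end
    study driver compares the three boundary-condition variants against the
    three-dimensional profile used as reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
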