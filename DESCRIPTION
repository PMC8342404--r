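Package: morphocontract
Title: One-Dimensional Morphoelastic Modelling of Post-Burn Skin Contraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates post-burn skin contraction with a one-dimensional
    morphoelastic continuum model coupling signaling molecules, fibroblasts,
    myofibroblasts, collagen, tissue velocity and effective strain. Provides
    the closed-form equilibrium relations of the model, linear stability
    analysis of the continuous problem via Fourier modes and of the
    semi-discrete problem via Von Neumann analysis, a moving-grid linear
    finite-element solver with backward Euler time integration and monolithic
    Picard iterations, scenario generators for wound and perturbed-equilibrium
    initial conditions, and drivers for grid-convergence and
    stability-validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
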