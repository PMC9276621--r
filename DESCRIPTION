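Package: scaffoldwave
Title: Multiphase Moving-Boundary Model of Tissue Growth in a Porous Scaffold
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates and analyses a multiphase moving-boundary model of
    engineered tissue growth in a rigid porous scaffold. The cell volume
    fraction obeys a degenerate nonlinear reaction-diffusion equation on a
    domain bounded by a moving tissue edge that is advected with the cell
    velocity (a Stefan-type condition). The package provides the constitutive
    pressure and diffusivity functions and their non-dimensionalisation, a
    boundary-fixed method-of-lines solver for the moving-boundary system, a
    phase-plane shooting method for the travelling-wave speed of the tissue
    front, closed-form small-growth-rate asymptotic solutions (cosh-ansatz
    profiles, implicit front law, stationary front position, interior-layer
    similarity profile), and a classifier for the three large-time regimes of
    the tissue edge: linear, logarithmic and stationary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
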