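Package: lvbulk
Title: Inverse Finite-Element Identification of Left-Ventricular
    Myocardial Bulk Modulus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies the time-varying bulk modulus (inverse
    compressibility) of the human left-ventricular wall over a cardiac
    cycle by inverse finite-element analysis. Builds a truncated-ellipsoid
    left-ventricle model with a rule-based myofiber and collagen
    architecture, a two-term Ogden matrix with a tunable volumetric
    stiffness, pressure-dependent active myofiber elastance, follower
    cavity-pressure loading and an epicardial elastic foundation, and
    per-time-step root finding of the bulk modulus so that the computed
    cavity volume matches a target pressure-volume cycle to within a
    prescribed relative error. Includes a synthetic cardiac-cycle waveform
    generator, a quasi-static total-Lagrangian nonlinear solver with
    mean-dilatation hexahedra, forward simulation for parameter-recovery
    studies, and a command-line pipeline with YAML configuration, CSV/JSON
    results and VTK mesh export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
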