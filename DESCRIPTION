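Package: wingfem
Title: Landmark-Based Wing-Vein Frame Models and Wind-Load Deformation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing flight-structural robustness of
    insect wings from landmark-based venation shapes. Generates synthetic
    two-dimensional hindwing landmark data for western corn rootworm variants,
    performs generalized Procrustes alignment to extract per-variant mean-shape
    vein wireframes, idealizes them as three-dimensional space frames of
    Euler-Bernoulli beam elements, loads them with dynamic wind pressure
    distributed onto the vein skeleton, and solves linear (and optionally
    geometrically nonlinear) static deformation across a grid of wind speeds.
    Includes wing aspect-ratio computation, mesh-refinement convergence
    studies, and cross-variant deformation comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    tools,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    deSolve,
    withr
Config/testthat/edition: 3
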