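Package: mmcadapt
Title: Mesh Optimization and Analytic Jacobian Rescaling for Mesh-Based
    Monte Carlo Optical Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and validating time-resolved forward models
    for fluorescence molecular tomography on tetrahedral meshes.  Includes a
    desk-scale mesh-based Monte Carlo photon transport kernel producing
    time-gated Green's functions, forward-adjoint assembly of sensitivity
    (Jacobian) matrices with fluorophore lifetime convolution, per-node
    solution and size fields, iterative size-field-driven mesh adaptation by
    edge collapse and edge split, sparse inverse-distance transformation
    matrices that rescale Jacobians onto adapted meshes without new
    stochastic simulation, and time-gated accuracy metrics (TPSF and nodal
    errors).  Synthetic slab and elliptical-slice phantoms with transmission
    optode layouts make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
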