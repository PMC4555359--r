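Package: phasecell
Title: Simulation and 3D Substructure Reconstruction of Nucleated Cells from
    Orthogonal Quantitative Phase Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation of quantitative phase microscopy images of
    parametric blood-cell models (piecewise-constant refractive-index scenes
    built from ellipsoids, spheres, biconcave discs and swept tubes), phase
    wrapping and two-dimensional phase unwrapping, inflexion-curve detection of
    the nucleus/cytoplasm and cell/medium interfaces on two orthogonal
    projection planes, and reconstruction of the nucleus as a surface of
    revolution or merged orthogonal-outline surface with quantitative shape
    reporting (center, fitted semi-axes, equivalent volume, ellipsoidal
    degree).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
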