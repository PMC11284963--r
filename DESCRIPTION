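Package: deltafr
Title: Surface-Registration Assessment of 3D Femoral Rotation Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional change in femoral angulation and
    rotation (delta-FR) between two triangulated bone-surface models of the
    same growing femur, using principal-axis prealignment, iterative closest
    point registration with an optional uniform scale, fractional sectioning
    into proximal and distal segments, and decomposition of the relative
    section rotation into Euler angles or a rotation vector. Includes a
    virtual-twist simulator that rotates the distal femur by known angles with
    a smooth axial ramp, a seeded generator of immature-femur-like surface
    meshes and their grown counterparts, and verification/validation harnesses
    with normalized detection, coefficient-of-variance and Bland-Altman
    agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
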