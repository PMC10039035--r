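Package: otolithmorph
Title: Joint Morphometrics of the Bony and Membranous Otolith System
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for joint 3D geometric morphometrics of the inner-ear
    otolith system, linking the bony vestibule (external structure) to the
    membranous utricle and saccule (internal structure). Provides
    generalized Procrustes superimposition with sliding semilandmarks under
    bending-energy minimization, principal component and ordinary
    least-squares regression batteries for shape and centroid size,
    two-block partial least squares integration tests and covariance-ratio
    modularity tests with permutation nulls, best-fit plane estimation of
    maculae orientation from bony landmark triads, spherical-harmonic
    (SPHARM) shape description of genus-zero surfaces, assembly of a mean
    morphometric model with a voxel-based perilymphatic negative-space
    mesh, and thin-plate-spline reconstruction of membranous soft tissue
    from bony landmarks with mesh-distance validation. A synthetic
    labyrinth generator with controlled covariation provides ground-truth
    populations for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
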