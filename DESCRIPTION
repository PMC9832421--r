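Package: zflex
Title: Continuous Flexibility Analysis of Cryo-EM Data with Zernike3D
    Deformation Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates smooth three-dimensional deformation fields from
    individual cryo-EM particle images by expanding the field in a basis of
    generalized Zernike radial polynomials and real spherical harmonics over
    the unit ball. Supports rotation of coefficient sets through the closure
    of the basis under rotations, cancellation of the unobservable field
    component along each particle's projection direction, transfer of
    coefficients across resolutions, warping of density maps and atomic
    models with a shared coefficient set, assembly and clustering of
    conformational landscapes in coefficient space, and motion-corrected
    algebraic reconstruction (ART and its deformation-aware variant ZART).
    Includes a synthetic-data generator producing phantoms, ground-truth
    deformation modes, and CTF-corrupted particle stacks with RELION-style
    STAR metadata so the full pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    bio3d
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse,
    uwot,
    withr
Config/testthat/edition: 3
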