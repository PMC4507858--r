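Package: shapevar
Title: Outline Shape Variables and the Comparison of Among-Group Ordinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Outline-based geometric morphometrics toolkit for studying how a
    shared direction of maximal within-group variance (Pmax) shapes the
    pictures of among-group differentiation given by principal component
    analysis, between-group principal component analysis and canonical
    variate analysis. Provides elliptic and radial Fourier decomposition of
    closed 2D outlines with zero-harmonic size standardization, variance
    decomposition (T = B + W) and the three ordinations plus principal
    coordinate analysis of a distance matrix, bootstrap comparison of
    group-wise first eigenvectors, Procrustes (Protest) comparison of
    group-mean configurations with a permutation test, a homogenized
    within-group-variance simulation study, a multivariate-normal synthetic
    data generator with configurable anisotropy, and an end-to-end analysis
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ade4
Config/testthat/edition: 3
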