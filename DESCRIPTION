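Package: seedshape
Title: Morphometric Analysis of Seed and Seed-Coat Cell Outlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative shape analysis of seed and seed-coat cell
    silhouettes. Extracts closed outlines from binary images, computes the
    eight general morphological descriptors (area, perimeter, Feret length
    and width, circularity, aspect ratio, roundness, solidity), measures
    similarity to parametric geometric seed models (cardioid-derived lateral
    and modified-ellipse dorsal families) through the J index, performs
    elliptic Fourier analysis with harmonic-power selection and a bilateral
    symmetry coefficient, and provides the univariate and multivariate
    statistical layer (PCA with group centroids, ANOVA with Tukey letters,
    Wilks MANOVA, two-sample Kolmogorov-Smirnov, assumption checks) used to
    compare genotype groups. A deterministic synthetic outline generator
    emulates populations differing in size, elongation, lobe undulation and
    asymmetry regime so the whole pipeline can be validated without raw
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    jsonlite,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
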