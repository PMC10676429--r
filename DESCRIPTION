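Package: finmorph
Title: 3D Landmark Geometric Morphometrics of Fish Body Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-dimensional landmark configurations of
    fish bodies: reading and writing 3D Slicer markups fiducial (.fcsv) files,
    Generalized Procrustes Analysis (translation, scaling and rotation of
    landmark configurations into a common shape space), principal component
    analysis of the resulting Procrustes coordinates, variance-weighted
    per-landmark eigenvector magnitudes summarising how much each landmark
    contributes to each shape axis, decomposition of total shape variance
    along the anteroposterior (length), dorsoventral (depth) and mediolateral
    (width) anatomical axes, centroid outlier scoring, and clade-wise
    morphospace occupancy via minimum convex hulls. A synthetic fauna
    generator builds landmark datasets from a template fish deformed by
    additive orthogonal shape modes with known ground truth, so the whole
    pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
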