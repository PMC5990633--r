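Package: spanol
Title: Spectral Parcellation of Genus-0 Cortical Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parcellation of closed genus-0 triangle meshes (cortical
    surfaces) into a chosen number of regions by k-means clustering of
    Laplace-Beltrami eigenfunctions, discretized with first-order finite
    elements (cotangent stiffness and consistent mass matrices).  Supports
    constrained clustering that excludes a labeled non-cortical region
    (cingulate-pole analogue), group co-parcellation by pooling
    sign-aligned eigenvector blocks across subjects, Hungarian relabeling
    of individual parcellations on a common spherical template, majority
    voting consensus maps, partition-comparison metrics (rand distance,
    Dice), geodesic distances between region boundaries and sulcal lines
    via fast marching, a rotation-based null model for the significance of
    partition agreement, and mean-curvature-flow stability analysis.
    Includes synthetic surface generators (icospheres, folded ellipsoids,
    polar constraint caps, plane-intersection sulcal lines) so every stage
    is testable without clinical data, plus readers and writers for GIFTI,
    OFF and PLY surfaces and GIFTI or plain-text label files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    RSpectra,
    RANN,
    clue,
    igraph,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
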