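Package: colonyspot
Title: Segmentation, Marked-Cell Detection and Intra-Colony Location
    Statistics for Stem-Cell Colony Images
Version: 0.1.0
Authors@R:
    person("Colony", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An automated pipeline for optical-microscopy images of
    embryonic stem cell colonies. Colonies are segmented with a two-phase
    region-based (Chan-Vese-type) level-set model after rolling-ball
    background removal, CLAHE contrast conditioning and border
    enhancement; the binary result is cleaned morphologically and split
    into individual colonies with a marker-controlled watershed on the
    Euclidean distance transform. Marked (gene-expressing) cells are
    detected inside colonies with an Orientation Matching transform over
    a band of radii after Perona-Malik anisotropic diffusion. Detections
    are converted to normalized centroid distances and normalized mutual
    distances, compared against a Monte-Carlo uniform-repopulation null
    model with two-sample Kolmogorov-Smirnov tests, and classified as
    PREFERENTIAL/NON-PREFERENTIAL, INNER/OUTER and
    CLUSTERED/NON-CLUSTERED. A phantom generator produces synthetic
    colony images and point patterns with controllable spatial structure
    so every stage is testable without microscope data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    jpeg,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
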