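Package: seedlingmix
Title: Segmentation, Completion and Leaf-Area Phenotyping of Seedling Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing single-view, top-down depth-camera point
    clouds of melon-type seedlings: a neighborhood-space-constraint filter
    that removes hover points and sparse outliers while retaining thin stems;
    a self-supervised occlusion dataset generator that removes the points
    nearest to synthetic viewpoints; a mixer-based encoder/decoder network
    (trained with hand-derived gradients, CPU only) for semantic and instance
    segmentation and progressive leaf completion; Chamfer, earth-mover and
    F-score metrics together with confusion-table segmentation scores; and
    leaf-area estimation by projected Delaunay triangulation with a
    correlation analysis against ground truth. A synthetic seedling generator
    with analytic leaf areas makes the whole pipeline testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
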