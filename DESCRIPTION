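Package: osteomatch
Title: Virtual Re-Association of Fragmented Skeletal Remains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for computer-aided reassembly of fragmented bones from
    computed tomography data. Provides seeded region-growing segmentation of
    CT volumes, iso-surface extraction to triangle meshes, fixed-size point
    cloud subsampling, per-point roughness fields for fracture-surface
    segmentation, correspondence-seeded trimmed iterative-closest-point
    registration, iterative merge-and-reassemble of fragment sets, and the
    evaluation battery used to compare reconstructions against intact
    reference bones (cloud-to-cloud distances, coverage, summary statistics,
    paired correlations). A fully ground-truthed synthetic long-bone
    generator supports end-to-end validation with known fragment poses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
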