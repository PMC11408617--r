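Package: spatialniche
Title: Spatial Niche Detection and Signature Scoring for Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects cellular neighborhoods and spatial communities in segmented
    multiplexed imaging data (CODEX-style cell tables) by k-nearest-neighbor
    composition profiling, per-sample k-means over-clustering, and
    enrichment-guided merging; quantifies nearest-cell-type distances with
    pixel-to-micrometer calibration; scores spot-level gene signatures on
    Visium-style count matrices with expression-bin-matched control genes; and
    ships a synthetic tissue generator that plants known niches so every stage
    can be validated against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
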