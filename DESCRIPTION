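Package: organoidmorph
Title: Topological Shape Descriptors and Bile-Canaliculi Network Features
    for Liver Organoid Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification toolkit for liver organoid and assembloid imaging.
    Implements a smooth Euler characteristic transform (SECT) shape descriptor
    for 2D organoid outlines, its temporal extension (DETECT) with a
    rotation-aligned distance and the d1/d0 distance-ratio score of
    morphological change, and distance-based clustering of ball versus
    bubbly/grape-like morphologies. Also implements a 3D two-channel
    bile-canaliculi segmentation pipeline (median filtering, IsoData
    thresholding, channel overlap, inflate/fill-holes/deflate lumen completion,
    size and border filtering, local thickness, homotopy-preserving
    skeletonization) with skeleton-network feature extraction (largest-network
    length, triple/quadruple junction counts, branch diameter distributions),
    second-harmonic-generation fibrillar-collagen integrated-density readouts,
    exact Mann-Whitney comparisons, and seeded synthetic-data generators
    (outlines, time courses, tube-network phantoms) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
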