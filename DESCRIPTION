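Package: voxseg
Title: Probabilistic Cell Segmentation for Imaging-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Unsupervised cell segmentation for imaging-based spatial
    transcriptomics (10x Xenium, Vizgen MERSCOPE, NanoString CosMx).
    Cell boundaries are represented on a voxel lattice and sampled with a
    connectivity-preserving Metropolis-Hastings scheme driven by a
    hierarchical Gamma-Poisson model of gene expression, with transcript
    repositioning under a Normal-mixture diffusion prior to model RNA
    leaking away from its source cell.  Includes readers for the common
    platform transcript-table dialects, writers for MatrixMarket / CSV /
    GeoJSON outputs, a synthetic-tissue generator with known ground truth,
    a spurious co-expression benchmark, and absorbing random-walk
    proximity analysis on Delaunay cell-neighborhood graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    data.table,
    deldir,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
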