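Package: chromomorph
Title: Clustering and Classification of Single-Cell 3D Chromosome Morphologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects prevalent morphology states in ensembles of single-cell 3D
    chromosome structures. Per-structure normalized distance matrices are
    embedded by a two-step dimension reduction (a convolutional autoencoder
    followed by t-SNE) and clustered by kernel-density peak detection with a
    watershed-like basin assignment. Per-cluster profiles place each state in
    the nuclear topography: contact and distance matrices, insulation-score
    territory-domain boundaries, radial position, radius of gyration, A/B
    compartments, nuclear-speckle distance and association (SpD, SON TSA-seq,
    SAF), and inter-chromosomal proximity (IPP). External single-cell
    observations (chromatin-tracing structures, sparse single-cell Hi-C
    contact maps imputed by random walk with restart) can be classified
    against the detected clusters. Includes seeded synthetic-data generators
    (planted conformational clusters, confined self-avoiding homopolymer
    negatives, planted speckle architectures, sparse single-cell contact
    maps) used as positive and negative controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    vegan
Config/testthat/edition: 3
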