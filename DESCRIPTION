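Package: atacsim
Title: Simulation of Single-Cell ATAC-seq Bin-by-Cell Count Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a per-cell-group statistical model from a single-cell
    ATAC-seq bin-by-cell count matrix (a Gaussian mixture model of
    log2 library sizes, per-bin non-zero cell proportions, and a quadratic
    relationship between non-zero proportions and normalized bin means) and
    samples synthetic bin-by-cell matrices from that model via
    Bernoulli-masked Poisson draws.  Includes genome binning from
    chrom.sizes files, sparse Matrix Market input/output with BED and
    barcode sidecars, conversion to peak-by-cell, region-by-cell and binary
    feature matrices, resemblance metrics (MAD, MAE, RMSE, Pearson
    correlation of bin summaries), clustering agreement scores (NMI, AMI,
    ARI), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
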