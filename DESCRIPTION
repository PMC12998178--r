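Package: splinegenes
Title: Fast Spline Modeling of Temporal and Spatial Gene Expression
    Patterns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits gene expression as smooth functions of pseudotime or of
    two-dimensional tissue coordinates using cubic B-spline and
    tensor-product least squares in which the design matrix is factorized
    once and shared across all genes, making the fit of thousands of genes
    a single matrix operation. Identifies temporally and spatially
    variable genes with exact F-tests or with a subsampling-permutation
    procedure whose null is calibrated by a fitted Gamma distribution,
    selects the number of internal knots per gene by BIC, and provides
    optional temporal/spatial binning, synthetic-data generators for
    benchmarking, plain-text and Matrix Market readers/writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    fitdistrplus,
    jsonlite,
    Matrix,
    optparse,
    splines,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
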