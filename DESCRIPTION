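Package: epicube
Title: Higher-Order Epistasis Analysis on Complete Binary Genotype Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing complete combinatorial genotype-phenotype
    landscapes over N biallelic positions into epistatic interaction terms of
    all orders, using both background-averaged (weighted Walsh-Hadamard) and
    single-reference transforms. Includes error propagation and significance
    calling for interaction terms, sparse (compressed-sensing) recovery of
    interaction spectra from subsampled phenotypes, estimation of first- and
    second-order epistasis from the statistics of thresholded functional
    sequence alignments, counting and connectivity analysis of functional
    single-mutation trajectories on the genotype hypercube, preprocessing of
    FACS-seq barcode count tables into calibrated brightness phenotypes, and
    synthetic-data generators that provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
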