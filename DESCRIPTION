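Package: bcstarprom
Title: Barcoded Synthetic Tandem-Repeat Promoter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for barcoded synthetic tandem-repeat promoter (BC-STAR-PROM)
    reporter screens, a massively parallel reporter assay that identifies
    signal-induced transcription factors from random synthetic promoters. Covers
    design of degenerate 20-nt barcodes and Hamming-separated sample indexes,
    tandem-repeat promoter and construct assembly, barcode-promoter association
    from circularization-junction and long reads (with in-silico restriction
    digestion), demultiplexing and barcode counting of screen reads, median
    normalization, fold-change and drug-response ranking, response-group
    clustering, PWM motif scanning and GSEA-style motif-set enrichment with a
    permutation null. Includes a synthetic-data generator with full ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
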