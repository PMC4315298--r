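Package: chromapack
Title: Local Chromatin Packing Analysis from Kilobase-Resolution Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing local chromatin packing in
    small plant genomes from kilobase-resolution Hi-C data. Provides in-silico
    restriction digestion and per-bin bias covariates, Hi-C read-pair
    classification and filtering, Poisson-regression bias normalization of
    binned contact matrices, a percentile-based strip index for calling bins
    with locally excessive or depressed contacts, directionality-index
    computation with three-state hidden-Markov segmentation and pattern
    grammars for insulator-like, TAD-boundary-like and TAD-interior-like
    regions, chromatin-state classification of epigenetic-mark tracks by
    k-means, and synthetic-data generators with planted ground truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
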