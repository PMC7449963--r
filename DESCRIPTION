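Package: footprintr
Title: Digital Genomic Footprinting for ATAC-Seq with Tn5 Bias Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for digital genomic footprinting of ATAC-seq data.
    Estimates the sequence preference of the Tn5 transposase as a
    dinucleotide weight matrix, computes expected and bias-corrected
    cutsite tracks, scores footprints with a combined
    depletion-plus-accessibility statistic, classifies transcription
    factor binding sites as bound or unbound with a two-component
    mixture model, tests differential TF binding between conditions,
    aggregates footprint profiles and footprint-depth metrics, clusters
    motifs by binding-site overlap, and infers TF-to-TF regulatory
    networks from promoter binding. Includes a seeded synthetic-data
    simulator with known bias and footprint ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    limma,
    mclust,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
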