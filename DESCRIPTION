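Package: mitovar
Title: Mitochondrial Variant and Heteroplasmy Analysis for Bulk and
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts mitochondrial genetic variation from aligned bulk and
    single-cell RNA-seq data. A pileup engine walks coordinate-sorted BAM
    files over the mitochondrial contig and tallies base calls per cell,
    supporting both well-based (one BAM per cell) and droplet-based (one
    barcoded BAM) layouts. The tallies are assembled into sparse
    alternative-allele-count and coverage matrices from which per-cell
    allele frequencies are computed. Downstream statistics include
    highly-variable site selection, per-site one-way ANOVA across donors,
    discriminative-germline identification, a heteroplasmy band scan,
    correlation-based cell-cell distances, t-SNE embedding and random-forest
    donor classification. A seeded read simulator generates complete
    synthetic studies (reference, donor genotypes, BAMs, truth tables) for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Matrix,
    Rsamtools,
    Rtsne,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
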