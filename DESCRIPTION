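Package: introcand
Title: Wild-Species Introgression Detection and Candidate-Gene
    Prioritization from Resequencing Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize the mosaic genome of an introgression-bred
    crop line from whole-genome resequencing variant calls and to prioritize
    candidate genes for a trait of interest.  The pipeline filters variant
    calls, detects highly polymorphic chromosome regions (putative wild
    introgressions) from 1-Mb window SNP/InDel densities, assigns a putative
    species origin per chromosome with neighbor-joining trees built from
    genotype-concordance distances across a multi-species accession panel,
    classifies variant effects and impact tiers against gene models,
    builds keyword-based candidate gene lists, colocalizes them with QTL
    intervals and polymorphic regions, compares promoters against a
    cis-regulatory element catalog, and classifies candidate-gene variants
    as shared with a wild donor or private.  A seeded simulator generates
    complete synthetic datasets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
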