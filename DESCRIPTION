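Package: gutevolve
Title: Within-Host Evolution Analysis of an Ingested Probiotic Strain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for studying the within-host adaptive evolution of a
    clonal bacterial strain from multi-isolate whole-genome resequencing:
    a strand-aware SNP filter cascade over per-isolate allele counts,
    neighbor-joining phylogenies rooted on the ancestral strain, distance to
    the most recent common ancestor (dMRCA) and six-class mutation spectra,
    gene-level parallel-evolution detection, mobile-element presence calls
    from coverage and depth, lineage (Muller) frequency dynamics with
    monotone Bezier interpolation, and resident-microbiome co-evolution
    statistics (CLR-based co-occurrence, competitor contrasts, and baseline-
    referenced SNP accumulation). Ships a forward-time simulator of clonal
    evolution with nested selected lineages that produces every input format
    with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
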