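Package: SpyTools
Title: Annotation, Divergence Dating and Integration-Site Profiling of
    Spy-Family DNA Transposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for the computational characterization of Spy-family
    cut-and-paste DNA transposons such as cgSpy from the Pacific oyster.
    Provides terminal-inverted-repeat (TIR) detection, multi-copy boundary
    refinement, copy counting under coverage/identity filters, transposase
    intactness classification and flank-motif / target-site-duplication
    analysis; Kimura two-parameter divergence estimation and
    divergence-vs-coverage landscapes; a ligation-mediated junction-library
    pipeline (read filtering, adapter trimming, mapping, >=10-read
    insertion-site calling with molecular-barcode deduplication);
    integration-site profiling (60-bp sequence logos, AAWTT target-motif
    fraction, fold-change enrichment against seeded random loci,
    five-criterion genomic-safe-harbor classification, Fisher exact
    comparisons); droplet-digital-PCR copy-number and LDH cytotoxicity
    calculators; and a fully seeded synthetic-data module (genomes, diverged
    element copies, junction libraries) with ground-truth tables so every
    stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SpyTools-package.R'
    'assayMath.R'
    'divergence.R'
    'elementAnnotation.R'
    'insertionPipeline.R'
    'io.R'
    'profiling.R'
    'simulate.R'
    'utils.R'
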