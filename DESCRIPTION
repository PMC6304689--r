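Package: heteropool
Title: Genomic Analysis of Heterotic Gene-Pool Development in Crop Panels
Version: 0.1.0
Authors@R:
    person("Maintainer", "Heteropool", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising how crop breeding pools diverge during
    hybrid-breeding programme development, modelled on resequencing panels of
    cultivated sunflower (open-pollinated varieties plus maintainer and
    restorer inbred pools). Provides hard-filtering of multi-sample VCFs,
    per-site and windowed Weir-Cockerham F_ST scans, LD-pruned principal
    component analysis, read-depth based gene presence/absence and
    amplification calling with permutation tests of gene-content
    differentiation, enrichment of gene loss inside wild-relative
    introgression blocks, classification of parallel versus opposite sorting
    of ancestral allele-frequency variation, and in-silico cross
    complementation of absent genes. Includes a fully seeded synthetic-panel
    generator with a ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
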