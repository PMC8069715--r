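Package: imprintKit
Title: Differential Methylation, Allelic Expression and CTCF Boundary Analysis
    for Imprinted Loci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising genomic imprinting at a single locus:
    calling differentially methylated regions (DMRs) between maternal-duplicate
    (parthenogenetic) and biparental methylomes from per-CpG methylation
    ratios, screening informative heterozygous SNPs from genomic-DNA allele
    depths and classifying per-tissue monoallelic expression from RNA allele
    counts, detecting CTCF-enriched topological boundary regions on coverage
    tracks with a biallelic-precipitation test, and annotating CpG islands and
    GC content on locus sequence. A seeded synthetic imprinted-locus generator
    with full ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
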