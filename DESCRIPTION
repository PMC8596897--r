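Package: cnvtriad
Title: Cross-Technology Characterization of Copy Number Variant Callsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates heterogeneous copy number variant (CNV) callsets from
    SNP arrays, short-read and long-read sequencing into quality-stratified
    CNV regions (CNVRs) and cross-technology CNV loci, and cross-validates
    every region against raw-data evidence from each technology: Log R Ratio
    shift in array probe intensities (Hellinger distance between in-region
    and flanking probe distributions), depth fold change in short-read
    coverage (duphold-style DHFFC/DHBFC), and long-read genotype
    concordance. Adds public-database presence/frequency lookup and genomic
    context annotation (segmental duplication coverage, flank GC,
    mappability). A seeded synthetic-data module generates every input the
    pipeline consumes so the full workflow runs end-to-end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
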