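Package: balscan
Title: Genome Scans for Balancing Selection Signatures in RAD-Seq Haplotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects genomic signatures of balancing and diversifying
    selection from RAD-seq haplotype data: per-locus haplotype diversity
    statistics (nucleotide diversity, gene diversity, observed
    heterozygosity), Gaussian kernel-smoothed windows centred on
    polymorphic loci with bootstrap significance of elevated diversity,
    AMOVA-based and Weir-Cockerham F_ST, sliding-window Tajima's D,
    merging of significant windows into candidate regions, overlap of
    multiple selection signatures, and a label-permutation test for
    enrichment of candidate gene classes (such as NLR disease-resistance
    genes) in high-diversity windows. Includes a synthetic-data generator
    with planted truth for end-to-end validation of the scan.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
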