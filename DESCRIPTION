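Package: methforge
Title: Bisulfite Sequencing Methylation Calling and Differentially
    Methylated Region Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular pipeline for the analysis of bisulfite sequencing
    data downstream of read alignment. Extracts per-cytosine methylation
    counts from coordinate-sorted BAM files against a reference genome,
    filters positions by coverage and sequence context, combines samples
    into groups with per-position summaries and overview statistics,
    aggregates methylation over annotation regions, detects differentially
    methylated regions (DMRs) by recursive segmentation of the group
    methylation difference signal combined with Mann-Whitney and
    two-dimensional Kolmogorov-Smirnov testing, and correlates DMR
    methylation with gene expression across samples. Includes a
    beta-binomial synthetic-data generator with known truth so every stage
    can be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    data.table,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
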