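Package: methmap
Title: Whole-Genome Bisulfite Methylome Analysis and Bulk Segregant Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies whole-genome bisulfite sequencing methylomes and maps
    causal loci in segregating populations. Provides per-cytosine methylation
    levels with a fourfold-coverage rule, context-resolved (CG/CHG/CHH)
    genome and feature summaries, chromosome-scale normalized methylation
    density profiles, and bisulfite conversion-rate QC from an unmethylated
    organellar genome. Calls differentially methylated regions (DMRs) with a
    sliding window of five same-context cytosines tested by Fisher's exact
    test and Benjamini-Hochberg FDR control, merges significant windows into
    regions of at least 200 bp, and annotates differentially methylated genes
    (DMGs) over gene bodies and 2 kb flanks. Includes bulk segregant analysis
    of pooled F2 allele counts and a synthetic-data module that generates
    reference sequences, planted DMRs, binomial bisulfite counts with
    conversion failure, an unmethylated chloroplast, gene annotations, and F2
    pool marker counts with full ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
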