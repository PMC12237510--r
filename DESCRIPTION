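Package: svweave
Title: Structural Variant Calling from Linked Reads by Barcode-Aware Local Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls insertions and deletions in the 50-10,000 bp range from
    synthetic long-read (linked-read) sequencing data, optionally augmented
    with low-coverage long reads. The reference is tiled into overlapping
    windows; per-window barcode selection recruits reads sharing those
    barcodes, including poorly aligned and unmapped mates, into a local de
    Bruijn graph assembly that preserves heterozygous structure and refuses
    contig extension across coverage drops. Contigs are realigned to the
    window with a seed-chain-extend glocal aligner and indels are read off
    the alignment CIGAR. Ships a diploid genome / linked-read / long-read
    simulator and a breakpoint-tolerance benchmarking module.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    Rsamtools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
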