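Package: mobilomekit
Title: Detection, Genotyping and Population Analysis of Transposable-Element
    Insertion Polymorphisms from Short Reads
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers non-reference transposable-element insertion
    polymorphisms (TIPs) from split-read and discordant-pair evidence in
    short-read alignments across many inbred accessions, genotypes
    presence/absence by negative coverage, and provides the downstream
    mobilome statistics used in population surveys: site-frequency spectra,
    presence/absence PCA, family accumulation curves with bootstrap
    confidence intervals, TIP-SNP linkage-disequilibrium profiling,
    mappability and density tracks, expression-impact metrics around
    insertions, and a kinship-corrected mixed-model association scan with
    carrier-label permutation control. Ships a deterministic mobilome
    simulator producing reference genomes, spiked accession genomes,
    paired-end reads and exact truth tables for hermetic benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    vegan,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
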