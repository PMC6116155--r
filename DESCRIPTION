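Package: microvir
Title: Recovery, Curation and Comparison of Complete Circular
    Microviridae Genomes from Metagenomic Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for recovering complete circular Microviridae
    (ssDNA phage) genomes from virome assemblies and comparing the
    resulting communities. Detects circularly permuted contigs via
    terminal direct repeats, trims them to unit-length genomes,
    calls open reading frames on the circle, identifies the major
    capsid protein (MCP) against a reference panel and reorients
    genomes to its start codon, dereplicates genomes at the 95
    percent nucleotide-identity species cutoff, reduces genomes to
    ordered gene-synteny fingerprints, converts per-sample read
    recruitment into breadth-of-coverage presence/absence calls, and
    compares samples with binary Bray-Curtis, Jaccard and Euclidean
    dissimilarities, Venn partitions and average-linkage dendrograms.
    Includes a synthetic-data generator that emulates microvirus-like
    circular genomes, assembly overrun artifacts, point-mutation
    divergence and controlled coverage so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
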