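Package: cghcnv
Title: Array-CGH Copy Number Variant Calling and Breakpoint Mechanism
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-channel comparative genomic hybridization (CGH)
    surveys of copy number variation (CNV) in inbred plant genomes. Designs
    variable-length oligonucleotide probes with k-mer repeat masking and
    uniqueness filtering, groups them into 10-probe contig fragments,
    normalizes two-channel intensities with a generalized-log transform,
    calls per-fragment CNVs with a two-component Gaussian mixture fitted by
    expectation maximization, summarizes the genome-wide CNV landscape
    (frequency spectrum, chromosome and window densities, recombination
    correlation, exon overlap), confirms CNVs at the sequence level through
    orthologous alignment and indel extraction, and classifies indel
    formation mechanisms (single-strand annealing, synthesis-dependent
    strand annealing, template slippage) against a random-breakpoint null.
    A synthetic-data generator with mechanism-tagged structural variants
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
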