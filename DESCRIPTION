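Package: snpscope
Title: Region-Scoped Querying and Analysis of SNP/INDEL Variation Panels
Version: 0.1.0
Authors@R:
    person("snpscope", "developers", email = "snpscope@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring large genomic variation panels one region or
    gene at a time: indexed VCF retrieval into an in-memory genotype matrix,
    site filtering by minor allele frequency and missingness, haplotype
    collapsing and minimum-spanning-tree haplotype networks, neighbour-joining
    trees and principal-coordinates analysis from identity-by-state distances,
    codon-level variant effect classification against GFF3 gene models,
    per-group allele frequencies for lollipop-style displays, geographic
    projection of single-site allele states, and sample-specific consensus
    sequences produced by substituting variants into the reference. A
    synthetic-fixture generator emits coherent VCF/FASTA/GFF3/metadata sets
    with machine-readable truth tables so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    ape,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
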