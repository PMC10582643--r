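Package: amplitax
Title: Taxon Relationships, Sex and Hybrid Parentage from Amplicon Panel
    Variant Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring relationships among closely related dioecious
    tree taxa (poplars of sections Aigeiros and Tacamahaca) from targeted
    amplicon sequencing panels. Reads multi-sample VCFs with per-sample
    allelic depths, builds variant allele frequency (VAF) matrices over named
    locus sets, computes pairwise-complete Euclidean distance matrices with
    missing-data rescaling, clusters samples with Ward's D2 criterion and
    exports Newick trees, genotypes sex from sex-determining region (SDR)
    coverage and clustering, infers the maternal and paternal species of
    interspecific hybrids from chloroplast and male-restricted SDR mean
    distances, and assigns accessions of uncertain affiliation by consensus
    across locus sets. A seeded synthetic amplicon-panel simulator with a
    ground-truth table supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    ape,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
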