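Package: motifSpacer
Title: Spacer-Length Profiling of Co-Occurring Cis-Regulatory Motif Pairs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome- and promoter-wide analysis of co-occurring
    cis-regulatory element pairs (by default the Dof-family AAAG core and
    the bZIP-family ACGT core) separated by variable-length spacers.
    Provides strand-aware 1-kb promoter extraction from FASTA/GFF3,
    exhaustive motif-pair scanning over a spacer range in both
    orientations, coverage-normalized per-spacer frequency profiles and
    promoter-versus-genome enrichment, shuffled-tetramer control queries,
    GC-adjusted per-position consensus calling over collected spacer
    sequences, a gene-set likelihood-of-occurrence statistic for
    condition-regulated genes, K-means clustering of gene-by-spacer
    occurrence matrices with silhouette-based model selection, and a
    seeded synthetic-data generator (i.i.d. genomes at a target GC
    content, gene models with full-length promoters, planted motif pairs,
    condition gene sets with a configurable lift) so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: MotifDiscovery, SequenceMatching, GeneRegulation, Clustering
RoxygenNote: 7.3.3
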