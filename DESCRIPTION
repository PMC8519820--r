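Package: ldscaffold
Title: Haplotype-Guided Genome Assembly Scaffolding from Population Variation
Version: 1.0.0
Authors@R:
    person("The ldscaffold authors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Detects shared haplotype "variation fingerprints" between segments
    of a draft genome assembly from a multi-sample population VCF, scores
    segment relations with an occurrence-normalized Jaccard similarity, lifts
    them to a contig adjacency graph, resolves unambiguous linear contig
    orders, and scaffolds contigs with physical evidence (mate-pair links,
    long-read alignments, contig-end overlaps). Ships a founder-mosaic
    population and fragmented-assembly simulator with known truth so the whole
    pipeline can be exercised and benchmarked offline, together with
    closed-form utilities for k-mer genome-size estimation and linkage
    disequilibrium decay.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    stats,
    utils,
    Biostrings,
    VariantAnnotation,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
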