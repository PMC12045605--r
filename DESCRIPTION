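Package: cretargets
Title: Calling Transcription-Factor Target Genes from Enhancer Epigenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for nominating direct transcription-factor
    target genes from epigenomic peak data. Active enhancers are derived by
    intersecting ATAC and H3K27Ac peaks and removing promoter- and
    exon-overlapping regions; candidate cis-regulatory elements are softly
    assigned to all transcription start sites within a distance window;
    element sequences are scanned with position weight matrices using exact
    p-values computed by dynamic programming; and genes are called as
    putative targets when they are expression-enriched and receive at least
    one motif-bearing element. Companion tools cross-reference targets
    against disease loci with a one-tailed enrichment test, compute
    ChIP-qPCR percent-input statistics with ratio paired t-tests, and
    generate fully ground-truthed synthetic studies so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
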