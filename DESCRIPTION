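Package: lncgland
Title: Long Non-Coding RNA Identification, Differential Expression and
    Regulatory Network Analysis for Two-Group RNA-Seq Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis pipeline for long non-coding RNA
    (lncRNA) studies with a two-group design, such as old versus young
    laying-hen uterus (shell gland) transcriptomes. Starting from a
    transcript annotation (GTF), transcript sequences (FASTA) and a
    fragment-count matrix, the package identifies lncRNA candidates by a
    consensus of three coding-potential predicates (ORF length, ORF
    coverage, hexamer usage), quantifies expression as FPKM with
    gene-level aggregation, calls differential expression with a
    TMM-normalized negative-binomial exact test, predicts cis targets by
    genomic-window search and trans targets by expression correlation,
    assembles the lncRNA-mRNA regulatory network with Cytoscape-readable
    exports, runs hypergeometric term enrichment against user-supplied
    annotations, and validates fold changes from qPCR Ct tables by the
    2^-ddCt method. A synthetic-data generator with planted truth makes
    every stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    xml2,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    edgeR
Config/testthat/edition: 3
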