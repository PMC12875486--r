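Package: dgrkit
Title: Quantification Toolkit for Reconstituted Diversity-Generating
    Retroelements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for experiments that reconstitute a
    diversity-generating retroelement (DGR) in a bacterial host:
    trinucleotide-context profiling of adenine-specific reverse-transcriptase
    errors from amplicon sequencing, an exact analytic codon-fate model for
    stop-codon conversion and accessible amino acids, signature-gated
    quantification of DGR-mediated target editing, repair-frequency arithmetic
    for colony-count assays, and orientation-aware transposon-insertion
    (Tn-seq) enrichment analysis with Mann-Whitney testing and
    replication-origin recentering. A synthetic-data generator with known
    ground truth exercises every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
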