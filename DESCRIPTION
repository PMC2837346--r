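Package: mircascade
Title: Small RNA Sequencing Tag Classification and Novel microRNA Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for small RNA deep-sequencing analysis:
    adapter trimming and collapsing of reads into counted unique tags,
    subtractive classification against known pre-miRNA, transcriptome and
    genome references by perfect-match alignment, prediction of novel miRNA
    candidates by hairpin folding combined with a stochastic context-free
    grammar classifier and abundance / rRNA / exon post-filters, isomiR and
    mature:star arm-ratio annotation, mirtron and genomic-context
    classification, and Pearson-correlation hierarchical clustering of miRNA
    expression profiles. Includes a synthetic-data module that generates toy
    genomes, gene models and simulated small RNA libraries with ground truth
    so that every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
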