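Package: mirforge
Title: Small RNA-Seq microRNA Discovery, Curation, and Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a desk-scale, fully testable small RNA-seq microRNA
    analysis pipeline for insect genomes: adapter trimming and read filtering,
    seed-and-extend genome mapping with at most one mismatch, read-stack
    detection, hairpin excision and base-pair-maximisation folding, a six-rule
    manual-curation engine with a three-of-six verdict, mature miRNA
    quantification, genomic-context classification and 5 kb cluster detection,
    cross-species conservation calling against reference catalogs, and
    three-predictor consensus target prediction over 1000 nt putative 3'UTRs.
    A deterministic synthetic-data generator plants ground-truth pre-miRNA
    hairpins and decoy loci into simulated genomes so every stage can be
    validated against a known truth set.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
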