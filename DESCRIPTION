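Package: circensus
Title: Consensus Back-Splice Junction Calling and CircRNA Characterisation
Version: 0.1.0
Authors@R:
    person("circensus", "maintainers", email = "circensus@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for characterising the circular RNA
    (circRNA) repertoire of paired tumour/normal RNA-seq cohorts from the
    outputs of multiple back-splice junction callers. Harmonises the output
    dialects of find_circ, circRNA_finder, CIRI2 and CIRCexplorer2 into a
    common coordinate frame, applies multi-caller consensus and
    high-confidence filters, builds raw and normalised junction-by-sample
    expression matrices, annotates host genes by coordinate intersection,
    performs negative-binomial Wald differential expression with
    Benjamini-Hochberg correction, scores per-sample hallmark back-splicing
    activity with a rank-based single-sample enrichment walk, classifies
    circRNA/host-gene concordance, profiles overlap against a pan-cancer
    reference catalogue, and provides correlation, contingency and survival
    association statistics. A seeded synthetic-data generator with planted
    truth makes every stage testable without any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    survival,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
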