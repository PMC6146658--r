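Package: tfstressnet
Title: Transcription-Factor Family Inventory and Stress-Response Networks for
    Allopolyploid Crops
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for characterizing large transcription-factor
    (TF) families in an allopolyploid plant genome and their responsiveness to
    abiotic stress. Provides rule-based TF family and subfamily classification
    from protein-domain hit tables, chromosome-distribution statistics,
    IUPAC-consensus promoter scanning for cis-regulatory elements,
    synteny-based gene gain/loss categorization against diploid ancestors,
    differential-expression calling with a noise-distribution probability,
    grey relational (grey correlation coefficient) co-expression network
    construction, bipartite GO-process projection networks with hypergeometric
    enrichment, and directed regulatory-network analysis including homolog
    label transfer and triangle-motif counting. A synthetic-data module
    generates every input with known ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
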