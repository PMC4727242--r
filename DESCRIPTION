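Package: locusq
Title: Quantitative Co-Regulation Analysis of an Intergenic miRNA Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement engine and analysis pipeline for studying the
    transcriptional co-regulation of an intergenic microRNA cluster
    (miR-200c/141) with its upstream gene (PTPN6). Provides absolute qPCR
    quantification from BAC standard curves, 2^-ddCt relative expression,
    read-through transcript ratios along the locus, a neighbourhood
    Transcription Correlation Score (TCS) with a permutation null,
    copy-number-based patient subgrouping, chromosome conformation capture
    (3C) interaction-frequency profiling with in-silico restriction
    digestion, and MeDIP/ChIP enrichment normalization. A synthetic-data
    generator emulating the qPCR measurement model makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
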