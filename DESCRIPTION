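Package: tagdge
Title: Tag-Based Digital Gene Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for tag-based digital gene expression
    (DGE/SAGE-style) profiling against an assembled transcript reference.
    Builds the virtual library of all CATG+17 nt tags from both strands of a
    reference transcript set, filters raw 49 nt reads into clean 21 nt tags
    with copy numbers, maps tags allowing at most one mismatch in the
    variable region, quantifies per-gene expression in tags per million
    (TPM), calls differentially expressed genes between two libraries with
    the Audic-Claverie exact count statistic under Benjamini-Hochberg FDR
    control, and tests gene sets for hypergeometric term enrichment. A
    bundled simulator generates reference transcriptomes, truth tables and
    raw tag libraries with known fold changes, sequencing errors and
    contaminant reads so the whole pipeline can be exercised against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
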