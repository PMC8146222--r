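Package: coexscreen
Title: Weighted Co-Expression Network Screening of Candidate Regulatory
    lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate regulatory long non-coding RNAs from bulk
    FPKM expression matrices by signed weighted gene co-expression network
    analysis: expression filtering, soft-threshold selection by scale-free
    topology fit, topological overlap, average-linkage clustering with a
    tree-variant dynamic cut, eigengene-based module merging, intramodular
    connectivity ("essential gene") ranking, overlap with differential
    expression results, and a time-course correlation screen for upstream
    regulators with exact t-distribution p-values. Includes relative qPCR
    quantification arithmetic and synthetic-data generators with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer,
    mclust
Config/testthat/edition: 3
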