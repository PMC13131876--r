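Package: xnetconserve
Title: Cross-Species Cell-Type-Specific Co-Expression Network Conservation
    and Regulon Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying conserved transcriptomic networks between
    two species from single-nucleus RNA-seq data. Implements anchor-based
    cross-species integration with species- and condition-specific cluster
    flagging, metacell-based consensus weighted gene co-expression module
    detection with eigengene differential testing, a three-criterion
    cross-species module conservation caller based on shared hub genes and
    hypergeometric membership overlap, and overlay of external gene
    regulatory networks onto differentially expressed gene sets to rank and
    intersect candidate master-regulator transcription factors. Includes a
    synthetic data generator with planted cell types, modules, condition
    effects, and regulons so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
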