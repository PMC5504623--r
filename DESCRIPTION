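Package: corrseg
Title: Detection of Chromosomal Regions of Correlated Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects chromosomal regions of correlated gene expression by
    block-diagonal segmentation of the gene-gene correlation matrix. For
    each chromosome, an exact dynamic programming algorithm finds the
    maximum-likelihood partition of the ordered genes into blocks of
    equicorrelated (compound-symmetric) expression, the number of blocks
    is chosen by a slope-heuristic penalized criterion, and each block is
    tested against the chromosomal background correlation with an exact
    scaled chi-square test. Expression can optionally be corrected for
    copy-number variation beforehand by segmenting per-patient SNP
    profiles into piecewise-constant means, mapping them to genes and
    regressing them out. Simulation generators with exchangeable and
    Wishart-perturbed block correlation, and gene- and region-level
    ROC/AUC evaluation utilities, are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
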