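Package: episcreen
Title: Integrative Methylome, Hydroxymethylome and Transcriptome Analysis
    for Paired Tumor/Normal Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Window-based quantification of MeDIP-seq and hMeDIP-seq
    fragment enrichment (RPM), groupwise sliding-window calling of
    differentially methylated and hydroxymethylated regions between
    matched tumor/normal pairs, Audic-Claverie differential expression
    with consensus calling across pairs, genome-scale pattern statistics
    (binned 5mC/5hmC regression and slope comparison, PCA group
    separation, element and anchored metaprofiles), and a directional
    multi-omics screen for candidate epigenetically repressed genes.
    Includes a synthetic-data generator that emulates a six-pair paired
    tumor/normal study with planted differential regions, a global tumor
    5hmC depletion and promoter-coupled expression changes, so every
    stage of the pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    data.table,
    cluster,
    yaml,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
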