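Package: stemGRN
Title: Enhancer Prediction and Regulatory Network Inference for Planarian Stem Cells
Version: 0.1.0
Authors@R:
    person("Maintainer", "stemGRN", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts enhancer-like regions in planarian adult stem cells from
    H3K27ac/H3K4me1 ChIP-seq peak proximity, profiles genes by FACS-compartment
    (X1/X2/Xins) proportional expression with an information-content scalar and a
    seven-way enrichment classification, assembles transcription-factor to target
    gene regulatory networks from ATAC-seq footprints falling inside enhancers
    (nearest-TSS target assignment), and validates the networks against RNAi
    differential-expression sets with a closed-form observed/expected link
    statistic and permutation p-values. Includes a fully deterministic
    synthetic-data generator with ground truth so that every stage is testable
    without any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
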