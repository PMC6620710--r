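Package: rddmcoloc
Title: Colocalization of Argonaute Binding Sites with Promoter DNA
    Methylation and COBRA Repeat-Methylation Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide colocalization analysis linking Argonaute
    (AGO1-AGO4) CLIP binding sites to promoter tiling-array DNA
    methylation: chain-file coordinate liftover, multimapper filtering
    and perfect/approximate match classification of mapped CLIP reads,
    proximity classification of methylation probes, 2x2 contingency
    tables with odds ratio, Wald 95% confidence interval and chi-square
    test, promoter-level Pearson correlation, proximity and TSS-relative
    binding profiles. Also implements COBRA (combined bisulfite
    restriction analysis) band-intensity formulas that quantify global
    LINE-1 and Alu methylation, and delta-delta-Ct fold changes. A
    seeded synthetic-data generator with planted ground truth emulates
    promoter arrays, CLIP mappings and gel lanes so the whole pipeline
    is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
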