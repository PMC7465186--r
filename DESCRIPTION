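Package: liquidmix
Title: Multi-Analyte Liquid Biopsy Analysis for Castration-Resistant
    Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a multi-analyte liquid biopsy pipeline for
    castration-resistant prostate cancer: circulating tumor cell (CTC)
    calling from per-cell rolling-circle-product (RCP) transcript counts
    with control-derived cut-offs, whole-blood RT-qPCR expression calling
    by delta-Cq thresholding against negative controls, shallow
    whole-genome plasma copy-number analysis with LOWESS GC correction,
    penalized least-squares segmentation and a six-criterion focal
    amplification caller, and per-patient integration of all assays into
    informativeness, resistance and concordance summaries. A fully seeded
    synthetic cohort generator emulates every input so the complete
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
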