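Package: atacdyn
Title: Temporal Chromatin Accessibility Dynamics and Regulatory Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of ATAC-seq time courses of cell differentiation:
    median-of-ratios normalization, pairwise negative-binomial Wald tests and
    intrinsic-variance filtering for differential accessibility, hierarchical
    clustering of peaks and samples into differentiation stages, position
    weight matrix scanning and hypergeometric motif enrichment, transcription
    factor footprint aggregation, promoter-based TF-TF regulatory network
    construction with expression-correlation edge typing, and change-point
    analysis of the chronology of accessibility, expression, and phenotype.
    Includes a seeded synthetic data generator emulating an 8-timepoint,
    2-replicate differentiation design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    yaml,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
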