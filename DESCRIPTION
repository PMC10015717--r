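Package: devstab
Title: Developmental Stability and Evolutionary Diversity of Embryonic
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies developmental stability of gene expression from
    inbred sibling-pair designs and relates it to expression diversity in
    hybrid descendants and wild populations. Implements per-gene pairwise
    variation statistics with a running-median correction for
    mean-expression dependence, a technical-error gene filter based on the
    Wilcoxon rank-sum test, a per-pair whole-transcriptome variance
    statistic for stage-level stability, and the nonparametric inference
    layer (Spearman test of no correlation, Kruskal-Wallis, Steel-Dwass
    all-pairs comparisons). A synthetic-data generator reproduces the
    statistical structure of the sibling/hybrid/wild design so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
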