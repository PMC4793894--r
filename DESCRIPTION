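Package: pathwaybench
Title: Pathway Activity Scoring and Cross-Dataset Consistency Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements six pathway activity scoring approaches under one
    roof: signed perturbation propagation on pathway graphs (SPIA-style),
    centrality-weighted overrepresentation (CePa-ORA style), a simplified
    network-based gene set statistic built on a signed influence matrix
    (NetGSA-style), the jackknifed Fisher exact test (EASE score, as in
    DAVID), gene set enrichment analysis with sample-label permutation, and
    principal-curve deregulation scoring per sample (Pathifier-style).
    Around the scorers it provides fixed preprocessing (log2(x+1) scaling,
    probe collapsing by highest variance, Welch-t differential expression
    with Benjamini-Hochberg FDR), a cross-dataset consistency score that
    rewards pathways reproduced across data sets and penalises false
    positives on artificial null data, and synthetic generators for
    expression data, signed pathway graphs and control-only null data sets,
    so the whole comparison can be exercised without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
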