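Package: netrel
Title: Test-Retest Reliability of Graph Metrics in Channel-Space
    Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs channel-space functional connectivity networks from
    two-session resting-state hemoglobin (fNIRS) time series and quantifies
    the test-retest reliability of graph-theoretical network metrics.
    Provides a synthetic-data generator with a planted reliability level,
    preprocessing utilities (modified Beer-Lambert conversion, zero-phase
    band-pass filtering, ICA-based artifact removal), Pearson correlation
    network construction across a sparsity sweep, global and nodal graph
    metrics with degree-preserving and correlation-matrix null models, and
    intraclass correlation coefficient (ICC) reliability analysis with
    threshold-independent area-under-curve summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
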