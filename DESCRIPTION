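Package: popmatch
Title: Marker-Based Population Matching and Artifact-State Detection for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning single-cell RNA-seq clusters to marker-defined
    populations via kNN-smoothed, rank-normalized expression scores aggregated
    at a percentile per cluster, with intermediate-state merging and
    minimum-score fallback; for building consensus stress and hypoxia gene
    signatures and classifying clusters as artifact states; for correcting cell
    states by regressing signature scores out of expression, quantified with a
    kNN mixing statistic; for generating synthetic droplet-style count matrices
    with planted populations, donors and state programs; and for fitting a
    two-regime log-log model to pipeline runtime scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
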