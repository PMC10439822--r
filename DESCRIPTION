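Package: goslimr
Title: GO Slim Annotation Transfer, Summarization, and Visualization for
    Gene Sets
Version: 0.1.0
Authors@R:
    person("goslimr", "developers", email = "goslimr@example.org",
           role = c("aut", "cre"))
Description: Summarizes the functional composition of nucleotide gene sets
    using GO slim categories transferred by homology. Starting from coding
    sequences and a tabular (BLAST outfmt-6 style) similarity search result
    -- either produced by an external search program or supplied
    precomputed -- the pipeline filters hits by E-value, alignment length,
    percent identity, and bitscore, selects one best hit per query under a
    configurable ranking metric, maps winning subjects to GO slim
    categories at gene-model and locus granularity, and tabulates raw
    counts and frequencies with annotation-coverage statistics. Tables
    from multiple gene sets can be outer-merged and rendered as pie
    charts, bar plots, raw and log-transformed heatmaps, and bubble
    graphs. Composition differences between a focal and a reference gene
    set are assessed with a chi-squared contingency test and Pearson
    residual based over/under-representation calls. A deterministic
    synthetic-fixture generator with planted ground truth makes the whole
    pipeline testable without downloads or external executables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
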