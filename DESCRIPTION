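Package: kinact
Title: Subcellular Kinome Activity Profiling from Peptide Microarrays
Version: 0.1.0
Authors@R:
    person("Kinact", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for serine/threonine kinase activity profiling
    on PamChip-style reporter-peptide microarrays. Converts multi-exposure
    kinetic intensity series to per-peptide slope signals, applies low-signal
    and linearity quality-control filters, computes within-chip log2
    fold-changes between sample groups with replicate averaging and
    nonparametric global tests, scores upstream kinases by a random-resampling
    enrichment statistic against a kinase-to-peptide substrate map, and
    harmonizes kinase rankings from multiple tools via percentile-rank
    normalization with a two-tool/0.75 mean-percentile selection rule.
    Includes a ground-truthed synthetic chip-data generator so that every
    stage of the pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    pheatmap,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
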