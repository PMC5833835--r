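Package: hicdynamics
Title: Differential Chromatin Interaction Analysis for Bridge-Linker Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline linking chromatin-conformation change to transcription
    regulation from bridge-linker Hi-C data: linker trimming and read-pair
    classification, binned contact matrices with iterative correction (ICE),
    A/B compartment calling from the first principal component of the
    observed/expected correlation matrix, per-TAD internal-interaction
    fold-change testing against an empirical replicate-derived null, an
    MA-plot binomial random-sampling test for differential promoter-enhancer
    (gene-regulatory) interactions, and downstream enrichment statistics
    (Fisher, Mann-Whitney, peak and network summaries). Ships a synthetic-data
    generator with planted ground truth (distance-decaying Poisson contacts,
    TAD blocks, compartment checkerboard, condition-specific interaction
    changes, peaks, expression, and linker-bearing read pairs) so every stage
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
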