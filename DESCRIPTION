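Package: dictytox
Title: Developmental Toxicity Assays and Pooled Mutant Screens in Dictyostelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies growth and developmental toxicity in the social amoeba
    Dictyostelium discoideum and classifies test compounds as teratogenic or
    nonteratogenic. Implements doubling-time estimation from time-lapse cell
    counts, LD50-anchored dose ladders, NOAEL/LOAEL calling, normalization and
    peak calling for developmental stage-reporter fluorescence time courses,
    the growth-LOAEL to development-NOAEL ratio classifier with predictivity
    metrics, selection analysis for pooled insertional-mutagenesis (REMI-Seq)
    screens (binned Z-scores on log fold changes, gene assignment, overlap and
    rank-quartile statistics, GO term over-representation), and scoring of
    competition-fitness and fluid-uptake validation assays. A synthetic-data
    module generates every input with the statistical structure the analyses
    assume, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    rtracklayer,
    GenomicRanges,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
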