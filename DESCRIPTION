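Package: zincspark
Title: Zinc Spark Quantification and Embryo Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies zinc sparks, the transient exocytotic release of zinc
    from mammalian eggs at activation, from fluorescence time-lapse recordings,
    and links spark profiles to preimplantation developmental outcome. Provides
    a synthetic-data generator for traces, image stacks and outcome-labelled
    cohorts with known ground truth; ROI definition (interior disk, perimeter
    annulus) and per-frame mean-intensity trace extraction from multi-page TIFF
    stacks; F/F0 baseline normalization, threshold-based spark detection and
    per-event profiling (amplitude, integrated intensity, duration, rate of
    rise); nucleus counting in confocal z-stacks; and cohort statistics
    (outcome grouping, reference-normalized comparisons, Z-score Spearman
    correlation of amplitude against embryo cell number, and percentile-split
    prospective selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    tiff,
    yaml,
    jsonlite,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
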