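Package: gonadscan
Title: Spatial Quantitation of Germline Stem-Cell Regulators Along the Gonad Axis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of protein and mRNA accumulation along the
    distal-proximal axis of the C. elegans germline, measured in cell-diameter
    (cd) coordinates. Provides wide-band linescan extraction from multi-channel
    confocal z-stacks, background subtraction against untagged controls,
    internal wild-type normalization, peak/base statistics, a genetic
    percent-contribution decomposition of peak protein levels across genotype
    panels, 3D smFISH focus detection with per-cell-diameter binning, and an
    expression pipeline (CPM, differential tests with Benjamini-Hochberg FDR,
    bound-gene intersection, degradation time-course primary/secondary target
    classification, half-life bounds, and delta-delta-Ct quantitation). A
    synthetic-data module generates image stacks, intensity-profile panels and
    negative-binomial count matrices with planted ground truth so that every
    stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    igraph,
    tiff,
    stats,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
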