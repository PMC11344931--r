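Package: nanosip
Title: Single-Cell Stable-Isotope Probing Analysis for NanoSIMS Ion Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying single-cell stable-isotope uptake from
    multi-plane NanoSIMS secondary-ion count images. Provides a synthetic
    scene generator for rod-shaped bacterial cells with Poisson ion counting,
    inter-plane drift estimation and plane accumulation, automatic cell
    segmentation, per-cell 13C/12C and 15N/14N isotope-ratio and
    atom-percent-enrichment quantification against natural-abundance
    baselines, rod and magnetosome-crystal morphometrics, normality-gated
    two-group comparisons, a subsample-median bootstrap polynomial trend fit
    with modal coefficient selection, and per-time-point heterogeneity
    profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
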