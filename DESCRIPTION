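Package: toposcreen
Title: Surface-Topography Screening Analysis for Marker-Positive Cell Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designed surface-topography (TopoChip-style) high-content
    screens of per-cell marker expression. Generates topography design libraries
    from geometric primitives with per-design descriptors (pattern area, space
    area, wave-number spectrum), simulates per-cell screening datasets with
    planted hit surfaces, computes cell-shape morphometrics from labelled masks,
    and runs the screening statistics end to end: interquartile-range quality
    control, control-calibrated per-chip adaptive intensity thresholding,
    chi-square hit calling against on-chip flat controls, and repeated
    random-forest classification with permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
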