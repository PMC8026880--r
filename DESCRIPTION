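Package: flyarena
Title: Single-Fly Arena Tracking and Locomotion Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for multi-sector single-animal arena assays: model the
    arena geometry (walled annular-wedge sectors, food-patch and virtual-patch
    regions of interest), track one dark animal per sector from long 1 Hz
    image sequences by temporal-median background subtraction and blob
    detection, apply quality control (missing-detection rates, exclusion,
    long-jump flagging), and compute locomotion and place-preference
    analytics (binned activity, stop-bout log2 histograms, displacement
    distributions and classes, ROI occupancy) with per-bin two-group
    Mann-Whitney comparisons. Includes a ground-truthed synthetic experiment
    generator (two-state stop/walk random walkers rendered onto IR-backlit
    style frames) so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    png,
    tiff,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
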