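Package: vitalscan
Title: Image-to-Survival Analysis for Scanner-Based Microfluidic Worm Arenas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Turns time-lapse flatbed-scanner image stacks of multi-arena
    microfluidic nematode chips into per-animal death times and survival
    statistics. Frames are aligned from user reference points, segmented into
    a rectangular arena grid, and thresholded; worm-like objects are measured
    and tracked by centroid displacement between hourly scans, with global
    frameshift compensation. Movement timelines are converted to death calls
    by a quiescence rule with censoring of survivors, then summarised as
    Kaplan-Meier curves, log-rank comparisons, and power-law LT50
    dose-response fits. A synthetic image-stack generator with ground-truth
    death times supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    survival,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
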