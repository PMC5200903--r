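Package: toscore
Title: Threshold Overlap Score Analysis for Two-Channel Colocalization
Version: 0.1.0
Authors@R:
    person("Packages", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rank-threshold colocalization analysis for two-channel
    microscopy signals. Computes the threshold overlap score (TOS), a
    rescaled ratio of observed to chance-expected pixel overlap above
    intensity thresholds, and the 9x9 TOS matrix over selected-fraction
    combinations together with its summary features (TOS at the highest
    thresholds, matrix maximum and minimum). Also provides reference
    implementations of the metrics TOS is commonly benchmarked against
    (Pearson and Spearman correlation, Manders M1/M2 under Costes
    automatic thresholding, and their chance-corrected differences),
    synthetic two-channel cell simulators (uniform null, two-population
    mixtures, condition-positive/negative ROC populations), Mann-Whitney
    and ROC evaluation utilities, extraction of per-cell pixel vectors
    from grayscale TIFF images via ImageJ ROI traces or integer count
    masks, and a command-line pipeline for cohort-level reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
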