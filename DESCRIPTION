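Package: clonalmosaic
Title: Clonal Architecture of Intestinal Tumors in Two-Color Mosaic Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-lineage (tdTomato red /
    EGFP green) mosaic intestinal whole mounts. Generates ground-truthed
    synthetic crypt mosaics and multi-founder tumors, binarizes two-channel
    fluorescence images into red/green/non-tissue label maps, computes the
    distance-map mosaic patch-size statistic, classifies per-tumor clonal
    architecture (heterotypic versus homotypic), and provides the statistical
    machinery linking mosaicism to observable heterotypy: the
    heterotypic-detection probability, estimation of the multi-ancestral
    tumor fraction, detection power, and proportion and rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
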