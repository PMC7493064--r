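Package: wbs2sdll
Title: Change-Point Detection via Wild Binary Segmentation 2 and Steepest
    Drop to Low Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects possibly frequent change-points in the mean (or median)
    of a univariate series. Wild Binary Segmentation 2 (WBS2) recursively
    builds a complete solution path of T-1 nested candidate change-points by
    maximising CUSUM contrasts over randomly sampled or deterministically
    gridded sub-intervals; the Steepest Drop to Low Levels (SDLL) rule then
    selects the model size at the steepest drop in the sorted candidate
    magnitudes, using thresholding only as a secondary check. Includes a
    robust variant based on sign CUSUMs of median-centred data for
    heavy-tailed or heteroskedastic noise, deterministic-grid sampling for
    bit-reproducible fits, multi-run stability frequencies, threshold
    calibration, synthetic-data generators (piecewise-constant signals,
    SETAR paths, random walks), and evaluation metrics.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
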