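Package: immobilitr
Title: Automated Immobility Scoring for Forced Swim and Tail Suspension Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated scoring of rodent immobility in forced swim test (FST)
    and tail suspension test (TST) videos. Each frame is segmented into a
    binary animal mask; the unsigned frame-to-frame change in mask area, as a
    percentage of the previous frame's area and averaged within each second,
    gives a per-second motion statistic that is thresholded into
    mobile/immobile states. Includes bout analytics (percent time immobile,
    latency to first immobility, longest bouts, block-wise immobility, raster
    intervals), ROC-based threshold calibration against manual per-second
    scores with transition-exclusion windows that compensate for human
    reaction lag, Bland-Altman and Pearson method-agreement statistics, and a
    ground-truthed synthetic video generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    tiff,
    png,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
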