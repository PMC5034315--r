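Package: glowtrack
Title: Simultaneous Molecular-Clock, Activity and Sleep Rhythms from
    Single-Fly Bioluminescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts time-lapse bioluminescence frame stacks of single
    flies held in capillary tubes into simultaneous molecular-clock,
    locomotor-activity and sleep time series, and quantifies rhythmicity,
    period and cross-rhythm coupling with paired single-fly statistics.
    Includes tray alignment from corner markers, projection-based tube
    detection, per-frame partitioning of exposure time into activity and
    rest from tube intensity profiles, sleep-episode assignment from
    stationary resting peaks, Butterworth detrending, an
    autocorrelation-based rhythmicity statistic with period estimation,
    and a synthetic frame-stack simulator with exported ground truth so
    that every stage is testable without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
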