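Package: devindexr
Title: Segmented Developmental Index Analysis for RT-qPCR Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Relative quantification of RT-qPCR panels by the delta-delta-Cq
    method, time-segmented classification of developmental gene trends by
    Pearson correlation, a composite developmental index (ratio of averaged
    up- to down-regulated gene expression) with per-segment ANCOVA comparison
    of maturation slopes between treatment arms, and factorial group
    statistics with Benjamini-Hochberg correction. Includes a synthetic
    Cq-table generator with a latent maturation clock and known ground truth,
    used to validate trend recovery, null calibration, and detection of a
    withdrawal-induced developmental delay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
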