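Package: ecgdelta
Title: Paired-Session ECG Segment Analysis of the Glucose Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how oral glucose intake changes nine ECG-derived
    per-beat segment series (RR/HRV, HR, R and P wave heights, QRS, PRQ, QT,
    QTc and ST). Provides a reproducible synthetic generator of paired
    glucose/control sessions with known ground truth, Pan-Tompkins R-peak
    detection and rule-based delineation, per-beat segment extraction,
    paired boxplot-delta statistics with direction classification,
    inter-segment correlation, Welch periodogram peak comparison, and a
    cohort scoring layer (direction percentages, status bands, change
    decisions and sensitivities) with tidy outputs and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
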