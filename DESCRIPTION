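Package: theilequity
Title: Theil Index Decomposition for Regional Health-Resource Equity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the equity of health-resource allocation across
    geographic units with the population-weighted Theil index (mean log
    deviation) and its exact within-/between-region decomposition.
    Provides validated province-year panel structures, per-capita and
    per-area density tables, extremal ratios, multi-year trend summaries,
    contribution-rate plots, and a synthetic-panel generator with
    controllable within- and between-region inequality for testing and
    calibration. Ships the 2013 cross-section of China's 31 provincial
    units as a packaged example data set.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
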