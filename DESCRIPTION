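Package: combindex
Title: Median-Effect Dose-Response Analysis and Combination-Index Synergy
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of two-drug combination experiments by the
    Chou-Talalay median-effect method. Fits the median-effect dose-response
    model (Dm, m) to control-normalized viability data by log-linear
    regression, computes the two-term combination index (CI) under Loewe
    additivity for constant-ratio designs, simulates Fa-CI profiles from
    fitted single-agent and mixture curves, and classifies CI values on the
    eleven-band verbal scale from very strong synergism to very strong
    antagonism. Includes a synthetic 96-well plate-data generator with known
    ground-truth parameters (per-agent Dm and slope, a constant target CI
    interaction mechanism, multiplicative plate-reader noise and replicate
    experiments) so every pipeline stage can be validated against truth, plus
    readers, writers and study-level report tables for long-format well data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
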