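Package: fermkin
Title: Off-Gas Growth Kinetics and Metabolite Profiling for Batch Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative physiology for submerged batch fermentations of
    filamentous fungi from bioreactor off-gas: carbon dioxide evolution rate
    and accumulated CO2 from exhaust composition and airflow, rule-based
    segmentation of growth into lag, exponential and non-exponential phases,
    maximum specific growth rates from dry weight and from accumulated CO2,
    biomass yields on substrate, and replicate summaries. Includes rule-based
    LC-MS molecular-feature counting and accurate-mass dereplication against a
    compound library, and a synthetic generator for batch fermentations and
    feature tables with known ground truth so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
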