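Package: fermbalance
Title: Carbon-Balance Accounting and Copy-Number Estimation for Raw-Starch
    Fermentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stoichiometric carbon-balance analysis of consolidated-bioprocessing
    (CBP) raw-starch ethanol fermentations: glucose-equivalent substrate
    accounting, CO2 inference from ethanol, an estimated-carbon-conversion
    statistic on a mol-carbon basis, theoretical ethanol yield and volumetric
    productivity. Also estimates integrated transgene copy number from
    sequencing-coverage ratios against a housekeeping-gene panel, converts
    amylase assay measurements to activity units, and generates synthetic
    fermentation time courses and coverage tables with known ground truth.
    Bundles a benchmark dataset of product, coverage and activity tables from
    amylolytic Saccharomyces cerevisiae strains fermenting 200 g/l raw corn
    starch.
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
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
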