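Package: edishr
Title: Interactive eDISH Analysis of Hepatic Safety Data from Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens clinical-trial laboratory data for drug-induced liver
    injury (DILI) signals. Reads SDTM-like, ADaM-like, or custom delimited
    lab tables, derives fold-of-upper-limit-of-normal statistics, R and nR
    liver-injury-pattern ratios, peak-time separation and an estimate of
    hepatocyte loss (P_ALT), classifies subjects into eDISH quadrants
    (possible Hy's Law, Temple's Corollary, hyperbilirubinemia, within
    range), and exports a fully self-contained interactive HTML report with
    participant drill-down profiles and an animated hysteresis plot. Ships
    a synthetic-trial simulator with known injury phenotypes so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
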