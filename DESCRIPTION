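Package: agedose
Title: Age-Based Reallocation of PET Dose and Scan Time with Radiation
    Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating an age-based acquisition protocol for
    FDG PET/CT in which the administered tracer activity and the scan
    time of the youngest and oldest patients in each study session are
    inversely modified by a fixed fraction (20% by default). Provides
    the dose/time reallocation scheduler, an effective-dose model
    linear in administered activity, additional-cancer-risk models
    (a calibrated age- and sex-specific coefficient table, and a
    BEIR VII-style lifetable engine), a seeded synthetic-cohort
    generator matching the study population's demographics, and
    stratified paired comparisons of risk under the reference and
    modified protocols. All user-facing functions take and return
    tidy data frames.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
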