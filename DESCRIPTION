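Package: newborntypes
Title: Classification and Prevalence of Vulnerable Newborn Types from Birth Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit, clean and analyse individual-level live-birth
    registry data for the study of vulnerable newborn types. Provides
    data-quality metrics (completeness, birthweight heaping index, extreme
    tail proportions), an ordered exclusion cascade with full flow
    accounting, classification of live births into six and ten newborn types
    from gestational age, size-for-gestational-age (against a user-supplied
    sex- and gestational-age-specific centile standard) and birthweight,
    country-year and national prevalence tables with median/IQR summaries by
    region, and 3-year moving-average time trends with change flagging. A
    synthetic multi-country registry generator with known ground truth
    (injected missingness, birthweight heaping and implausible records)
    supports end-to-end testing without access to confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
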