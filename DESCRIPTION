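Package: surveyfraud
Title: Point-Based Fraud Detection for Web-Based Survey Research
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a point-based protocol for detecting fraudulent
    entries in web-based survey research with geographic eligibility
    criteria. Eight rule-based criteria (IP geolocation with override
    logic, offline phone-directory line-type lookup, within-entry name
    consistency, alternating letter/digit email patterns, three
    cross-entry duplicate rules over contact items, and survey duration)
    are scored per entry on a 0-10 point scale; entries are categorized
    as valid, potentially fraudulent, or fraudulent, and a recontact
    verification state machine resolves final categories. Includes a
    deterministic canonical fixture reconstructing a published study's
    entry-level violation patterns, a randomized labeled
    synthetic-respondent generator, descriptive reporting (criterion
    tables, categorization flow, IP-address sharing, geolocation
    breakdown), and a command-line interface.
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
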