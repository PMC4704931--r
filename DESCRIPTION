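Package: bbtagree
Title: Agreement Between Wearable Skin Temperature and Oral Basal Body
    Temperature for Ovulation Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates biphasic menstrual-cycle basal body temperature (BBT)
    series and overnight wearable skin-temperature streams with known ground
    truth, reduces minute-level streams to pre-waking basal values, classifies
    cycles as ovulatory, anovulatory or inconclusive by standard visual chart
    criteria and by a quantitative mean temperature method, and quantifies
    between-method agreement with Spearman rank correlation, Bland-Altman
    analysis and Cohen's kappa. Provides an end-to-end study pipeline that
    compares an oral digital thermometer against an armband skin-temperature
    device across a simulated cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    ggplot2,
    optparse,
    knitr
Config/testthat/edition: 3
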