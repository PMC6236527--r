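Package: gwtrace
Title: Trace-Element Occurrence and Drinking-Water Risk Assessment for
    Groundwater Monitoring Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarization and risk assessment of trace-element
    concentrations (arsenic, antimony, selenium) measured in shallow
    groundwater wells across land-use areas and seasons. Provides per-well
    and per-area summary statistics, drinking-water guideline exceedance and
    detection frequencies, paired seasonal comparison tests, the average
    daily dose / hazard quotient / hazard index non-carcinogenic risk
    cascade for adult and child cohorts, correspondence-analysis and
    principal-component ordination of the wells-by-analytes matrix, and a
    seeded zero-inflated lognormal simulator of monitoring campaigns with
    parameter recovery. Ships the per-well summary tables of a 35-well
    Ibadan (southwestern Nigeria, 2016) campaign as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
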