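# Shared builders for in-code fixtures.

# A small balanced campaign: wells in one area, seasons x 3 months, one
# analyte, concentrations supplied per well as list(wet = c(...), dry = c(...)).
make_records <- function(conc_by_well, area = "residential", analyte = "antimony") {
  rows <- lapply(seq_along(conc_by_well), function(i) {
    per_season <- conc_by_well[[i]]
    dplyr::bind_rows(lapply(names(per_season), function(s) {
      tibble::tibble(
        well_id = sprintf("W%d", i),
        area = area,
        season = s,
        month_index = seq_along(per_season[[s]]),
        analyte = analyte,
        conc_ugL = per_season[[s]]
      )
    }))
  })
  dplyr::bind_rows(rows)
}

# The published area-by-cohort risk table (in-paper data), cells kept as
# printed strings so each comparison can use one unit in the value's last
# printed decimal. _a = adults, _c = children.
printed_risk_table <- function() {
  tibble::tribble(
    ~area, ~analyte, ~C, ~ADD_a, ~HQ_a, ~HI_a, ~ADD_c, ~HQ_c, ~HI_c,
    "residential", "arsenic", "0.00065", "0.000026", "0.0867", "2.7159", "0.0000325", "0.1083", "3.3948",
    "residential", "antimony", "0.0245", "0.00098", "2.45", "2.7159", "0.001225", "3.0625", "3.3948",
    "residential", "selenium", "0.0224", "0.000896", "0.1792", "2.7159", "0.00112", "0.224", "3.3948",
    "commercial", "arsenic", "0.0118", "0.000472", "1.5733", "4.1989", "0.00059", "1.9667", "5.2487",
    "commercial", "antimony", "0.0238", "0.000952", "2.38", "4.1989", "0.00119", "2.975", "5.2487",
    "commercial", "selenium", "0.0307", "0.001228", "0.2456", "4.1989", "0.001535", "0.307", "5.2487",
    "industrial", "arsenic", "0.00167", "0.0000668", "0.2227", "3.0199", "0.0000835", "0.2783", "3.7748",
    "industrial", "antimony", "0.0269", "0.001076", "2.69", "3.0199", "0.001345", "3.3625", "3.7748",
    "industrial", "selenium", "0.0134", "0.000536", "0.1072", "3.0199", "0.00067", "0.134", "3.7748",
    "agricultural", "arsenic", "0.000", "0.0000", "0.0000", "2.8772", "0.0000", "0.0000", "3.5965",
    "agricultural", "antimony", "0.0271", "0.001084", "2.71", "2.8772", "0.001355", "3.3875", "3.5965",
    "agricultural", "selenium", "0.0209", "0.000836", "0.1672", "2.8772", "0.001045", "0.209", "3.5965"
  )
}

# One unit in the last printed decimal of a number given as a string
# ("0.0245" -> 1e-4; "2.45" -> 1e-2).
print_unit <- function(s) {
  dec <- ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0)
  10^(-dec)
}

expect_matches_printed <- function(computed, printed_string) {
  expect_lte(
    abs(computed - as.numeric(printed_string)),
    print_unit(printed_string) * (1 + 1e-9)
  )
}
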