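# Non-carcinogenic risk cascade for drinking-water exposure:
#   ADD = DW * C / BW      (mg/kg/day; C in mg/L)
#   HQ  = ADD / RfD        (dimensionless)
#   HI  = sum of HQ over co-occurring analytes for one scenario.
# Exposure duration/frequency and averaging-time factors present in fuller
# EPA models are deliberately absent: the cascade is the simple intake form.

#' Average daily dose from drinking water
#'
#' `ADD = DW * C / BW`, where `DW` is daily water intake (L/day), `C` the
#' concentration in mg/L and `BW` body weight (kg).
#'
#' @param C Concentration in mg/L (`>= 0`); vectorized.
#' @param cohort A cohort row from [cohort_params()], or a cohort name
#'   (`"adult"`/`"child"`) for the default parameters.
#' @return ADD in mg/kg/day, at full precision.
#' @export
#' @examples
#' average_daily_dose(0.0245, "adult") # 0.00098
average_daily_dose <- function(C, cohort) {
  if (is.character(cohort)) cohort <- cohort_params(cohort)
  if (any(C < 0, na.rm = TRUE)) {
    gw_abort("concentration must be non-negative", "gw_validation_error")
  }
  if (cohort$BW <= 0 || cohort$DW <= 0) {
    gw_abort("cohort DW and BW must both be positive", "gw_validation_error")
  }
  cohort$DW * C / cohort$BW
}

#' Hazard quotient
#'
#' `HQ = ADD / RfD`: the ratio of the estimated exposure dose to the
#' reference dose below which no adverse effects are expected. `HQ > 1`
#' flags possible non-carcinogenic adverse effects.
#'
#' @param ADD Average daily dose, mg/kg/day (`>= 0`); vectorized.
#' @param RfD Reference dose, mg/kg/day (`> 0`).
#' @return HQ (dimensionless) with attribute `adverse_possible`
#'   (`HQ > 1`, logical, same length).
#' @export
#' @examples
#' hazard_quotient(0.00098, 0.0004) # 2.45
hazard_quotient <- function(ADD, RfD) {
  if (any(!is.finite(RfD)) || any(RfD <= 0)) {
    gw_abort("RfD must be positive", "gw_validation_error")
  }
  if (any(ADD < 0, na.rm = TRUE)) {
    gw_abort("ADD must be non-negative", "gw_validation_error")
  }
  hq <- ADD / RfD
  attr(hq, "adverse_possible") <- hq > 1
  hq
}

#' Hazard index
#'
#' Sum of hazard quotients over the analytes of one exposure scenario
#' (area by cohort). Exact, order-independent addition.
#'
#' @param hqs Numeric vector of HQ values.
#' @return HI (dimensionless).
#' @export
#' @examples
#' hazard_index(c(1.5733, 2.38, 0.2456)) # 4.1989
hazard_index <- function(hqs) {
  if (length(hqs) < 1) {
    gw_abort("need at least one HQ", "gw_validation_error")
  }
  sum(as.numeric(hqs))
}

#' Full risk table per area, cohort and analyte
#'
#' Runs the ADD/HQ/HI cascade for every requested land-use area and cohort:
#' `C` is the area mean of per-well overall means (ug/L, converted once to
#' mg/L), ADD and HQ follow per analyte, and HI sums the HQs within each
#' area-by-cohort scenario. On the packaged fixture this reproduces the
#' published risk table: 4 areas x 2 cohorts x 3 analytes = 24 rows and 8
#' HI values.
#'
#' `c_signif` optionally rounds `C` (mg/L) to a number of significant
#' figures (half-up, as the published table's values are rounded) before
#' the cascade; the default `NULL` keeps full floating precision.
#'
#' @param summaries A well-summary tibble.
#' @param registry Guideline registry providing `rfd` per analyte.
#' @param cohorts Tibble of cohorts ([default_cohorts()]).
#' @param areas Land-use areas to include (default: all four).
#' @param analytes Analytes to include (default: all three).
#' @param c_signif Significant figures for `C`, or `NULL` for full precision.
#' @return A tibble with columns `area`, `cohort`, `analyte`, `C_mgL`,
#'   `ADD`, `RfD`, `HQ`, `HI`, `hq_gt1`, `hq_gt2`; `HI` is repeated on the
#'   analyte rows it aggregates.
#' @export
#' @examples
#' rt <- risk_table(load_study_fixture(), c_signif = 3)
#' unique(rt$HI[rt$area == "commercial" & rt$cohort == "adult"]) # 4.1989
risk_table <- function(summaries,
                       registry = load_guideline_registry(),
                       cohorts = default_cohorts(),
                       areas = gw_areas(),
                       analytes = gw_analytes(),
                       c_signif = NULL) {
  missing_rfd <- setdiff(analytes, names(registry$rfd))
  if (length(missing_rfd)) {
    gw_abort(
      sprintf("registry provides no RfD for: %s", paste(missing_rfd, collapse = ", ")),
      "gw_config_error"
    )
  }
  grid <- tidyr::expand_grid(area = areas, cohort = cohorts$cohort, analyte = analytes)
  grid <- dplyr::left_join(grid, cohorts, by = "cohort")
  grid$C_mgL <- vapply(seq_len(nrow(grid)), function(i) {
    to_mg_per_L(area_mean(summaries, grid$analyte[i], grid$area[i]))
  }, numeric(1))
  if (!is.null(c_signif)) grid$C_mgL <- signif_half_up(grid$C_mgL, c_signif)
  grid$ADD <- grid$DW * grid$C_mgL / grid$BW
  grid$RfD <- unname(registry$rfd[grid$analyte])
  grid$HQ <- grid$ADD / grid$RfD
  grid <- dplyr::mutate(
    dplyr::group_by(grid, .data$area, .data$cohort),
    HI = sum(.data$HQ)
  )
  grid <- dplyr::ungroup(grid)
  grid$hq_gt1 <- grid$HQ > 1
  grid$hq_gt2 <- grid$HQ > 2
  grid[, c("area", "cohort", "analyte", "C_mgL", "ADD", "RfD", "HQ", "HI",
    "hq_gt1", "hq_gt2")]
}

# Round to n significant figures with ties away from zero (half-up), the
# rule the published table's 3-figure C values follow (0.02705 -> 0.0271);
# base signif() rounds to even and would give 0.027. The 1e-8 shift keeps
# decimal ties that land just under .5 in binary (0.01335 -> 133.4999...)
# on the half-up side; it is far below the data's printing precision.
signif_half_up <- function(x, digits) {
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - digits + 1
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / 10^e + 0.5 + 1e-8) * 10^e
  out
}
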