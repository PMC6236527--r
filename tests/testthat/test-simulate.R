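test_that("the calibrated configuration reflects the fixture's detection structure", {
  cfg <- calibrate_sim_config()
  p <- cfg$params
  get <- function(a, s, col) p[[col]][p$analyte == a & p$season == s]
  expect_equal(get("arsenic", "wet", "detect_prob"), 0)
  expect_equal(get("arsenic", "dry", "detect_prob"), 6 / 35)
  expect_equal(get("antimony", "dry", "detect_prob"), 1)
  expect_equal(get("selenium", "wet", "detect_prob"), 1)
  # dry-season antimony geometric mean near 47 ug/L
  expect_equal(exp(get("antimony", "dry", "log_gm")), 47, tolerance = 0.02)
  expect_equal(unname(cfg$wells_per_area[gw_areas()]), c(24L, 5L, 4L, 2L))
})

test_that("campaign generation is reproducible and respects degenerate configs", {
  cfg <- calibrate_sim_config()
  a <- generate_campaign(cfg, seed = 99)
  b <- generate_campaign(cfg, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 35 * 2 * 3 * 3)
  expect_false(identical(a$conc_ugL, generate_campaign(cfg, seed = 100)$conc_ugL))

  none <- cfg
  none$params$detect_prob <- 0
  rec <- generate_campaign(none, seed = 1)
  expect_true(all(rec$nondetect))

  exact <- sim_config(
    wells_per_area = c(residential = 2, commercial = 1),
    params = tibble::tibble(
      analyte = "antimony", season = c("wet", "dry"),
      detect_prob = 1, log_gm = log(24.9), log_gsd = 0
    ),
    area_multipliers = c(residential = 1, commercial = 2)
  )
  rec2 <- generate_campaign(exact, seed = 5)
  expect_equal(unique(rec2$conc_ugL[rec2$area == "residential"]), 24.9)
  expect_equal(unique(rec2$conc_ugL[rec2$area == "commercial"]), 49.8)
})

test_that("invalid configurations are rejected field by field", {
  base <- tibble::tibble(
    analyte = "antimony", season = "dry",
    detect_prob = 0.5, log_gm = 1, log_gsd = 0.5
  )
  expect_error(
    sim_config(params = dplyr::mutate(base, detect_prob = 1.2)),
    "detect_prob", class = "gw_validation_error"
  )
  expect_error(
    sim_config(params = dplyr::mutate(base, log_gsd = -1)),
    "log_gsd", class = "gw_validation_error"
  )
  expect_error(
    sim_config(params = base[, -1]),
    "analyte", class = "gw_schema_error"
  )
  expect_error(
    sim_config(params = base, area_multipliers = c(residential = 0)),
    class = "gw_validation_error"
  )
  expect_error(generate_campaign(calibrate_sim_config()),
    class = "gw_validation_error")
})

test_that("parameters are recovered from a large seeded campaign", {
  cfg <- calibrate_sim_config()
  # scale the design up, preserving area proportions: 24/5/4/2 wells x 20
  cfg$wells_per_area <- cfg$wells_per_area * 20
  camp <- generate_campaign(cfg, seed = 1234)
  est <- recover_parameters(camp)
  joined <- merge(est, cfg$params, by = c("analyte", "season"))
  for (i in seq_len(nrow(joined))) {
    expect_lt(abs(joined$detect_prob_hat[i] - joined$detect_prob[i]), 0.02)
    if (joined$n_detected[i] > 1) {
      se <- joined$log_gsd[i] / sqrt(joined$n_detected[i])
      expect_lt(abs(joined$log_gm_hat[i] - joined$log_gm[i]), 3 * se + 1e-12)
    } else {
      expect_false(joined$estimable[i] && joined$n_detected[i] > 1)
    }
  }
  # the never-detected stratum is flagged inestimable, not an error
  as_wet <- est[est$analyte == "arsenic" & est$season == "wet", ]
  expect_false(as_wet$estimable)
  expect_true(is.na(as_wet$log_gm_hat))
})

test_that("noiseless degenerate configurations are recovered exactly", {
  exact <- sim_config(
    wells_per_area = c(residential = 5),
    params = tibble::tibble(
      analyte = c("antimony", "antimony"), season = c("wet", "dry"),
      detect_prob = 1, log_gm = c(log(10), log(40)), log_gsd = 0
    )
  )
  est <- recover_parameters(generate_campaign(exact, seed = 3))
  expect_equal(est$detect_prob_hat, c(1, 1))
  expect_equal(sort(est$log_gm_hat), sort(c(log(10), log(40))))
  expect_equal(est$log_gsd_hat, c(0, 0))
})

test_that("expected concentrations follow the zero-inflated lognormal mean", {
  cfg <- sim_config(
    wells_per_area = c(residential = 1),
    params = tibble::tibble(
      analyte = "selenium", season = c("wet", "dry"),
      detect_prob = c(0.5, 1), log_gm = log(10), log_gsd = c(0, 0.5)
    )
  )
  manual <- mean(c(0.5 * 10, 1 * 10 * exp(0.5^2 / 2)))
  expect_equal(expected_mean_concentration(cfg, "selenium", "residential"), manual)
})

test_that("simulated pipeline HI agrees with its closed-form expectation", {
  cfg <- calibrate_sim_config()
  cfg$wells_per_area <- c(residential = 150, commercial = 150,
    industrial = 150, agricultural = 150)
  camp <- generate_campaign(cfg, seed = 77)
  s <- summarize_wells(camp)
  rt <- risk_table(s)
  for (ar in gw_areas()) {
    hi_obs <- rt$HI[rt$area == ar & rt$cohort == "adult"][1]
    hi_exp <- expected_hi(cfg, ar, "adult")
    # Monte-Carlo error of the area-mean-driven HI, from the per-well spread:
    # HI is linear in the three area means, so its SE follows from the
    # per-well overall means of each analyte
    reg <- load_guideline_registry()
    co <- cohort_params("adult")
    well_hi <- rowSums(sapply(gw_analytes(), function(a) {
      sub <- s[s$analyte == a & s$scope == "overall" & s$area == ar, ]
      (co$DW * to_mg_per_L(sub$mean) / co$BW) / reg$rfd[[a]]
    }))
    se <- sd(well_hi) / sqrt(length(well_hi))
    expect_lt(abs(hi_obs - hi_exp), 4 * se)
  }
})
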