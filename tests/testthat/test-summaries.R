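test_that("summarize_wells reproduces hand-computed seasonal and overall statistics", {
  rec <- make_records(list(
    list(wet = c(0, 2, 4), dry = c(10, 12, 14)),
    list(wet = c(1, 1, 1), dry = c(5, 6, 7))
  ))
  s <- summarize_wells(rec)
  w1 <- s[s$well_id == "W1", ]
  expect_equal(w1$mean[w1$scope == "wet"], 2)
  expect_equal(w1$mean[w1$scope == "dry"], 12)
  # balanced design: overall mean = mean of seasonal means = mean of all 6
  expect_equal(w1$mean[w1$scope == "overall"], 7)
  expect_equal(w1$sd[w1$scope == "overall"], sd(c(0, 2, 4, 10, 12, 14)))
  expect_equal(w1$min[w1$scope == "overall"], 0)
  expect_equal(w1$max[w1$scope == "overall"], 14)
  expect_equal(w1$n[w1$scope == "overall"], 6L)
})

test_that("metropolis-wide means match the published general averages", {
  fx <- load_study_fixture()
  as_ <- metropolis_mean(fx, "arsenic")
  sb <- metropolis_mean(fx, "antimony")
  se <- metropolis_mean(fx, "selenium")
  expect_equal(as_$mean, 2.32, tolerance = 0.05 / 2.32)
  expect_equal(sb$mean, 24.9, tolerance = 0.05 / 24.9)
  expect_equal(se$mean, 22.5, tolerance = 0.05 / 22.5)
  expect_equal(sb$n_wells, 35L)
  expect_gt(sb$sd, 0)
})

test_that("a single well's metropolis mean is its own mean", {
  one <- tibble::tibble(
    well_id = "W1", area = "residential", analyte = "arsenic",
    scope = "overall", mean = 5, sd = 0, min = 5, max = 5
  )
  expect_equal(metropolis_mean(one, "arsenic")$mean, 5)
  expect_error(metropolis_mean(one[0, ], "arsenic"), class = "gw_validation_error")
})

test_that("area means reproduce the published risk-table concentrations", {
  fx <- load_study_fixture()
  expect_equal(area_mean(fx, "arsenic", "commercial"), 11.82)
  expect_equal(area_mean(fx, "arsenic", "agricultural"), 0)
  # (26.3 + 26.8 + 30.3 + 24.2) / 4, hand-summed from the overall table
  expect_equal(area_mean(fx, "antimony", "industrial"), 26.9)
  expect_error(area_mean(fx, "arsenic", "wetland"), class = "gw_validation_error")
})

test_that("metropolis mean equals the well-count-weighted mean of area means", {
  fx <- load_study_fixture()
  n_wells <- c(residential = 24, commercial = 5, industrial = 4, agricultural = 2)
  for (a in gw_analytes()) {
    weighted <- sum(vapply(names(n_wells), function(ar) {
      n_wells[[ar]] * area_mean(fx, a, ar)
    }, numeric(1))) / sum(n_wells)
    expect_equal(metropolis_mean(fx, a)$mean, weighted)
  }
})

test_that("detection frequencies match the published detection claims", {
  fx <- load_study_fixture()
  expect_equal(detection_frequency(fx, "arsenic"), 6 / 35)
  expect_equal(detection_frequency(fx, "antimony"), 1)
  expect_equal(detection_frequency(fx, "arsenic", scope = "wet"), 0)
})

test_that("guideline exceedance counts wells against the WHO limits", {
  fx <- load_study_fixture()
  sb <- exceedance(fx, "antimony", 20)
  expect_equal(sb$n_exceeding, 26L)
  expect_equal(sb$fraction, 26 / 35)
  expect_equal(exceedance(fx, "antimony", 20, scope = "dry")$fraction, 1)
  expect_equal(exceedance(fx, "selenium", 40)$n_exceeding, 4L)
  # the dry-season selenium claim needs the inclusive comparison:
  # GW27 sits exactly at 40.0
  expect_equal(exceedance(fx, "selenium", 40, scope = "dry")$n_exceeding, 10L)
  expect_equal(exceedance(fx, "selenium", 40, scope = "dry", inclusive = TRUE)$fraction,
    11 / 35)
  expect_error(exceedance(fx, "selenium", -1), class = "gw_validation_error")
})

test_that("exceedance fraction is monotone in the limit and in inclusivity", {
  fx <- load_study_fixture()
  for (a in gw_analytes()) {
    limits <- c(1, 5, 10, 20, 40, 60, 80)
    fr <- vapply(limits, function(l) exceedance(fx, a, l)$fraction, numeric(1))
    expect_true(all(diff(fr) <= 0))
    for (l in limits) {
      expect_gte(
        exceedance(fx, a, l, inclusive = TRUE)$fraction,
        exceedance(fx, a, l)$fraction
      )
    }
  }
})

test_that("pearson_r is the product-moment correlation with validated input", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_error(pearson_r(c(1, 2, 3), c(1, 1, 1)), class = "gw_degenerate_error")
  expect_error(pearson_r(1:2, 1:2), class = "gw_validation_error")
  # affine invariance: positive slope preserves r, negative slope flips it
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)
    r <- pearson_r(x, y)
    expect_equal(pearson_r(2.5 * x + 3, y), r)
    expect_equal(pearson_r(-1.5 * x + 1, y), -r)
  }
})

test_that("wet vs dry selenium correlation across wells is near the published value", {
  fx <- load_study_fixture()
  wet <- fx[fx$analyte == "selenium" & fx$scope == "wet", ]
  dry <- fx[fx$analyte == "selenium" & fx$scope == "dry", ]
  wet <- wet[order(wet$well_id), ]; dry <- dry[order(dry$well_id), ]
  expect_equal(pearson_r(wet$mean, dry$mean), 0.6125, tolerance = 0.02 / 0.6125)
})

test_that("the paired seasonal t-test matches its closed form and flags antimony", {
  fx <- load_study_fixture()
  res <- paired_seasonal_ttest(fx, "antimony")
  expect_true(res$significant)
  expect_equal(res$df, 34)
  expect_gt(res$mean_difference, 0)  # dry season higher

  # brute-force oracle: t = mean(d) / (sd(d) / sqrt(n))
  set.seed(21)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    wet <- runif(n, 0, 30); dry <- runif(n, 10, 60)
    recs <- make_records(lapply(seq_len(n), function(j) {
      list(wet = rep(wet[j], 3), dry = rep(dry[j], 3))
    }))
    res_i <- paired_seasonal_ttest(summarize_wells(recs), "antimony")
    d <- dry - wet
    expect_equal(res_i$statistic, mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-12)
  }
})

test_that("degenerate seasonal differences are handled explicitly", {
  same <- make_records(list(
    list(wet = c(1, 2, 3), dry = c(1, 2, 3)),
    list(wet = c(4, 5, 6), dry = c(4, 5, 6)),
    list(wet = c(7, 8, 9), dry = c(7, 8, 9))
  ))
  res <- paired_seasonal_ttest(summarize_wells(same), "antimony")
  expect_equal(res$statistic, 0)
  expect_false(res$significant)

  shifted <- make_records(list(
    list(wet = c(1, 1, 1), dry = c(2, 2, 2)),
    list(wet = c(3, 3, 3), dry = c(4, 4, 4)),
    list(wet = c(5, 5, 5), dry = c(6, 6, 6)),
    list(wet = c(7, 7, 7), dry = c(8, 8, 8))
  ))
  expect_warning(
    res2 <- paired_seasonal_ttest(summarize_wells(shifted), "antimony"),
    "diverges"
  )
  expect_equal(res2$p_value, 0)
})

test_that("one-way ANOVA matches hand computation and conserves sums of squares", {
  res <- anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$F, 13.5)
  expect_equal(res$ss_between, 13.5)
  expect_equal(res$ss_within, 4)
  expect_equal(c(res$df1, res$df2), c(1, 4))

  # brute-force oracle on random groups
  set.seed(31)
  for (i in 1:5) {
    g <- lapply(1:3, function(j) rnorm(sample(2:5, 1), mean = j))
    res_i <- anova_oneway(g)
    all_v <- unlist(g); gm <- mean(all_v)
    ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
    ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
    f <- (ssb / (length(g) - 1)) / (ssw / (length(all_v) - length(g)))
    expect_equal(res_i$F, f, tolerance = 1e-12)
    expect_equal(res_i$ss_between + res_i$ss_within, res_i$ss_total,
      tolerance = 1e-9)
  }
})

test_that("ANOVA rejects degenerate input and is calm under exchangeability", {
  expect_error(anova_oneway(list(a = c(1, 1), b = c(1, 1))),
    class = "gw_degenerate_error")
  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), class = "gw_validation_error")
  expect_error(anova_oneway(list(a = c(1, 2))), class = "gw_validation_error")
  set.seed(41)
  pooled <- rnorm(30)
  shuffled <- split(sample(pooled), rep(1:3, each = 10))
  expect_gt(anova_oneway(shuffled)$p_value, 0.05)
})
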