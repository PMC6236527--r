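#' Summarize raw monitoring records per well
#'
#' Collapses monthly records to per-well, per-analyte summaries at three
#' scopes: each season separately and `"overall"` across all samples. With
#' the balanced design (equal monthly samples per season) the overall mean
#' equals the unweighted mean of the two seasonal means, which is the
#' convention the packaged study tables follow. SDs use the sample (n-1)
#' convention.
#'
#' @param records A tibble of monitoring records as returned by
#'   [read_records_csv()] or [generate_campaign()].
#' @return A well-summary tibble with columns `well_id`, `area`, `analyte`,
#'   `scope`, `mean`, `sd`, `min`, `max`, `n`, compatible with
#'   [load_study_fixture()] output.
#' @export
summarize_wells <- function(records) {
  records <- validate_records(records)
  per_scope <- function(df, scope) {
    out <- dplyr::summarise(
      dplyr::group_by(df, .data$well_id, .data$area, .data$analyte),
      mean = mean(.data$conc_ugL),
      sd = stats::sd(.data$conc_ugL),
      min = min(.data$conc_ugL),
      max = max(.data$conc_ugL),
      n = dplyr::n(),
      .groups = "drop"
    )
    out$scope <- scope
    out
  }
  seasonal <- dplyr::bind_rows(lapply(GW_SEASONS, function(s) {
    per_scope(records[records$season == s, , drop = FALSE], s)
  }))
  overall <- per_scope(records, "overall")
  out <- dplyr::bind_rows(overall, seasonal)
  out[, c("well_id", "area", "analyte", "scope", "mean", "sd", "min", "max", "n")]
}

scope_means <- function(summaries, analyte, scope) {
  if (!analyte %in% GW_ANALYTES) {
    gw_abort(sprintf("unknown analyte: %s", analyte), "gw_validation_error")
  }
  if (!scope %in% GW_SCOPES) {
    gw_abort(sprintf("unknown scope: %s", scope), "gw_validation_error")
  }
  sub <- summaries[summaries$analyte == analyte & summaries$scope == scope, , drop = FALSE]
  if (nrow(sub) == 0) {
    gw_abort(sprintf("no %s summaries for %s", scope, analyte), "gw_validation_error")
  }
  if (anyDuplicated(sub$well_id)) {
    gw_abort("more than one summary per well in scope", "gw_validation_error")
  }
  sub
}

#' Metropolis-wide mean concentration
#'
#' Unweighted mean (and sample SD) of the per-well overall means across all
#' wells: the "general average" level of an analyte over the whole
#' monitored area.
#'
#' @param summaries A well-summary tibble ([load_study_fixture()] or
#'   [summarize_wells()]).
#' @param analyte One of `gw_analytes()`.
#' @param scope Summary scope, default `"overall"`.
#' @return A one-row tibble: `analyte`, `scope`, `mean`, `sd`, `n_wells`.
#' @export
#' @examples
#' metropolis_mean(load_study_fixture(), "arsenic") # mean 2.32 ug/L
metropolis_mean <- function(summaries, analyte, scope = "overall") {
  sub <- scope_means(summaries, analyte, scope)
  tibble::tibble(
    analyte = analyte, scope = scope,
    mean = mean(sub$mean), sd = stats::sd(sub$mean), n_wells = nrow(sub)
  )
}

#' Land-use area mean concentration
#'
#' Unweighted mean of the per-well overall means within one land-use area;
#' this is the concentration `C` that feeds the risk cascade (after
#' conversion to mg/L).
#'
#' @inheritParams metropolis_mean
#' @param area One of `gw_areas()`.
#' @return The area mean in ug/L (scalar).
#' @export
#' @examples
#' area_mean(load_study_fixture(), "arsenic", "commercial") # 11.82 ug/L
area_mean <- function(summaries, analyte, area, scope = "overall") {
  if (!area %in% GW_AREAS) {
    gw_abort(sprintf("unknown area: %s", area), "gw_validation_error")
  }
  sub <- scope_means(summaries, analyte, scope)
  sub <- sub[sub$area == area, , drop = FALSE]
  if (nrow(sub) == 0) {
    gw_abort(sprintf("no wells in area: %s", area), "gw_validation_error")
  }
  mean(sub$mean)
}

#' Detection frequency across wells
#'
#' Fraction of wells whose summary mean at the given scope is strictly
#' positive, i.e. wells where the analyte was detected at all (non-detects
#' are recorded as zero).
#'
#' @inheritParams metropolis_mean
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' detection_frequency(load_study_fixture(), "arsenic") # 6/35
detection_frequency <- function(summaries, analyte, scope = "overall") {
  sub <- scope_means(summaries, analyte, scope)
  mean(sub$mean > 0)
}

#' Guideline exceedance across wells
#'
#' Counts wells whose summary mean at the given scope exceeds a guideline
#' limit. The comparison is strict (`>`) by default; `inclusive = TRUE`
#' counts wells sitting exactly at the limit as exceeding (`>=`).
#'
#' @inheritParams metropolis_mean
#' @param limit Guideline limit in ug/L (`> 0`), e.g. from
#'   [load_guideline_registry()].
#' @param inclusive Use `>=` instead of `>`.
#' @return A one-row tibble: `analyte`, `scope`, `limit`, `inclusive`,
#'   `n_wells`, `n_exceeding`, `fraction`.
#' @export
#' @examples
#' exceedance(load_study_fixture(), "antimony", 20) # 26/35 = 0.743
exceedance <- function(summaries, analyte, limit, scope = "overall", inclusive = FALSE) {
  if (!is.numeric(limit) || length(limit) != 1 || !is.finite(limit) || limit <= 0) {
    gw_abort("limit must be a single positive number", "gw_validation_error")
  }
  sub <- scope_means(summaries, analyte, scope)
  hit <- if (inclusive) sub$mean >= limit else sub$mean > limit
  tibble::tibble(
    analyte = analyte, scope = scope, limit = limit, inclusive = inclusive,
    n_wells = nrow(sub), n_exceeding = sum(hit), fraction = mean(hit)
  )
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()] for paired well-level
#' values (e.g. wet-season vs dry-season means of the same wells).
#'
#' @param x,y Paired numeric vectors of equal length `>= 3`.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    gw_abort("x and y must be paired vectors of length >= 3", "gw_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    gw_abort("correlation undefined: zero variance", "gw_degenerate_error")
  }
  stats::cor(x, y, method = "pearson")
}

#' Paired seasonal comparison test
#'
#' Two-sided paired t-test on the per-well (dry - wet) differences of
#' seasonal means, with `df = n - 1`. The pairing reflects the design: the
#' same wells are measured in both seasons. When the differences have zero
#' spread but nonzero mean the t statistic diverges; the limiting p-value 0
#' is reported with a warning.
#'
#' @inheritParams metropolis_mean
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A one-row tibble: `analyte`, `statistic`, `df`, `p_value`,
#'   `alpha`, `significant`, `mean_difference` (dry - wet, ug/L),
#'   `pearson_r` (wet vs dry correlation over wells).
#' @export
#' @examples
#' paired_seasonal_ttest(load_study_fixture(), "antimony")$significant # TRUE
paired_seasonal_ttest <- function(summaries, analyte, alpha = 0.05) {
  wet <- scope_means(summaries, analyte, "wet")
  dry <- scope_means(summaries, analyte, "dry")
  wet <- wet[order(wet$well_id), , drop = FALSE]
  dry <- dry[order(dry$well_id), , drop = FALSE]
  if (!identical(wet$well_id, dry$well_id)) {
    gw_abort("every well needs both a wet and a dry seasonal mean", "gw_validation_error")
  }
  n <- nrow(wet)
  if (n < 3) {
    gw_abort("need at least 3 paired wells", "gw_insufficient_data_error")
  }
  d <- dry$mean - wet$mean
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      stat <- 0; p <- 1
    } else {
      warning("zero spread in seasonal differences; t statistic diverges, p -> 0")
      stat <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(dry$mean, wet$mean, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  r <- if (stats::sd(wet$mean) == 0 || stats::sd(dry$mean) == 0) {
    NA_real_
  } else {
    pearson_r(wet$mean, dry$mean)
  }
  tibble::tibble(
    analyte = analyte, statistic = stat, df = n - 1, p_value = p,
    alpha = alpha, significant = p < alpha,
    mean_difference = mean(d), pearson_r = r
  )
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA over groups of values (e.g. per-well means
#' grouped by land-use area), via [stats::lm()] behind a validated surface.
#' The decomposition satisfies `ss_between + ss_within = ss_total`.
#'
#' @param groups A named list of numeric vectors, each of length `>= 2`.
#' @return A one-row tibble: `F`, `df1`, `df2`, `p_value`, `ss_between`,
#'   `ss_within`, `ss_total`.
#' @export
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))$F # 13.5
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    gw_abort("need at least 2 groups", "gw_validation_error")
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    gw_abort("every group needs at least 2 values", "gw_validation_error")
  }
  values <- unlist(groups, use.names = FALSE)
  if (stats::sd(values) == 0) {
    gw_abort("all values identical: F is undefined", "gw_degenerate_error")
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::lm(values ~ g)
  tab <- stats::anova(fit)
  tibble::tibble(
    F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
    p_value = tab$`Pr(>F)`[1],
    ss_between = tab$`Sum Sq`[1], ss_within = tab$`Sum Sq`[2],
    ss_total = sum(tab$`Sum Sq`)
  )
}
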