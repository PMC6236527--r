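#' Run the full analysis pipeline
#'
#' Ties the modules together in the order of the study's analysis: per-well
#' summaries, metropolis and area means, guideline exceedance and detection
#' frequencies (overall and per season), paired seasonal tests, one-way
#' ANOVA across land-use areas, prevalence ordering, PCA and CA ordination,
#' and the area-by-cohort risk table. Output is a pure function of the
#' input data and configuration; when `out_dir` is given every table is
#' also written as CSV at full precision.
#'
#' @param records Monitoring records, or `NULL` to analyse the packaged
#'   study fixture (mutually exclusive with `fixture = TRUE` + records).
#' @param fixture Use the packaged per-well summary fixture instead of raw
#'   records (default when `records` is `NULL`).
#' @param registry Guideline registry ([load_guideline_registry()]).
#' @param limit_set Name of the limit set inside the registry (default
#'   `"WHO"`).
#' @param cohorts Cohort tibble ([default_cohorts()]).
#' @param out_dir Directory for CSV output, or `NULL` to skip writing.
#' @param c_signif Passed to [risk_table()]; `NULL` keeps full precision.
#' @return A named list of tibbles/objects: `well_summaries`,
#'   `metropolis_means`, `area_means`, `detection`, `exceedance`,
#'   `seasonal_tests`, `area_anova`, `prevalence`, `pca`, `ca`, `risk`,
#'   invisibly.
#' @export
run_full_pipeline <- function(records = NULL,
                              fixture = is.null(records),
                              registry = load_guideline_registry(),
                              limit_set = "WHO",
                              cohorts = default_cohorts(),
                              out_dir = NULL,
                              c_signif = NULL) {
  if (fixture && !is.null(records)) {
    gw_abort("supply either records or fixture = TRUE, not both", "gw_validation_error")
  }
  summaries <- if (fixture) {
    load_study_fixture()
  } else {
    if (nrow(tibble::as_tibble(records)) == 0) {
      gw_abort("no records supplied", "gw_validation_error")
    }
    summarize_wells(records)
  }
  if (!limit_set %in% names(registry$limits)) {
    gw_abort(sprintf("registry has no limit set named '%s'", limit_set), "gw_config_error")
  }
  limits <- registry$limits[[limit_set]]

  analytes <- intersect(GW_ANALYTES, unique(summaries$analyte))
  metro <- dplyr::bind_rows(lapply(analytes, function(a) {
    metropolis_mean(summaries, a)
  }))
  amean <- dplyr::bind_rows(lapply(analytes, function(a) {
    tibble::tibble(
      area = GW_AREAS, analyte = a,
      mean_ugL = vapply(GW_AREAS, function(ar) area_mean(summaries, a, ar), numeric(1))
    )
  }))
  detection <- dplyr::bind_rows(lapply(analytes, function(a) {
    dplyr::bind_rows(lapply(GW_SCOPES, function(s) {
      tibble::tibble(analyte = a, scope = s,
        fraction = detection_frequency(summaries, a, s))
    }))
  }))
  exceed <- dplyr::bind_rows(lapply(analytes, function(a) {
    dplyr::bind_rows(lapply(GW_SCOPES, function(s) {
      exceedance(summaries, a, limits[[a]], scope = s)
    }))
  }))
  seasonal <- dplyr::bind_rows(lapply(analytes, function(a) {
    paired_seasonal_ttest(summaries, a)
  }))
  area_groups <- lapply(analytes, function(a) {
    sub <- scope_means(summaries, a, "overall")
    groups <- split(sub$mean, sub$area)
    groups <- groups[vapply(groups, length, 1L) >= 2]
    if (length(groups) >= 2 && stats::sd(unlist(groups)) > 0) {
      cbind(analyte = a, anova_oneway(groups))
    } else {
      NULL
    }
  })
  area_anova <- dplyr::bind_rows(area_groups)
  prevalence <- prevalence_order(summaries)
  mat <- wells_matrix(summaries)
  # correlation-based PCA is the default; fall back to covariance when a
  # column is constant (e.g. an analyte never detected in a small campaign)
  pca <- tryCatch(
    pca_ordination(mat, standardize = TRUE),
    gw_validation_error = function(e) pca_ordination(mat, standardize = FALSE)
  )
  ca <- ca_ordination(mat)
  risk <- risk_table(summaries, registry = registry, cohorts = cohorts,
    c_signif = c_signif)

  out <- list(
    well_summaries = summaries,
    metropolis_means = metro,
    area_means = amean,
    detection = detection,
    exceedance = exceed,
    seasonal_tests = seasonal,
    area_anova = area_anova,
    prevalence = prevalence,
    pca = pca,
    ca = ca,
    risk = risk
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- out[!names(out) %in% c("pca", "ca")]
    for (nm in names(tables)) {
      write_table_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    for (ord in c("pca", "ca")) {
      obj <- out[[ord]]
      write_table_csv(
        data.frame(id = rownames(obj$row_coords), obj$row_coords),
        file.path(out_dir, paste0(ord, "_row_coords.csv"))
      )
      write_table_csv(
        data.frame(id = rownames(obj$col_coords), obj$col_coords),
        file.path(out_dir, paste0(ord, "_col_coords.csv"))
      )
      write_table_csv(
        data.frame(component = seq_along(obj$explained_fraction),
          explained_fraction = obj$explained_fraction),
        file.path(out_dir, paste0(ord, "_explained.csv"))
      )
    }
  }
  invisible(out)
}
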