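# Vocabulary of the monitoring design. Concentrations are stored in ug/L
# everywhere except at the risk-module boundary, where one explicit
# conversion to mg/L happens (see to_mg_per_L()).

GW_ANALYTES <- c("arsenic", "antimony", "selenium")
GW_AREAS <- c("residential", "commercial", "industrial", "agricultural")
GW_SEASONS <- c("wet", "dry")
GW_SCOPES <- c("overall", GW_SEASONS)

RECORD_COLUMNS <- c("well_id", "area", "season", "month_index", "analyte", "conc_ugL")

gw_abort <- function(msg, class) {
  stop(rlang::error_cnd(c(class, "gw_error"), message = msg))
}

#' Monitored analytes, land-use areas and seasons
#'
#' Accessors for the controlled vocabularies used throughout the package:
#' the three trace elements monitored (arsenic, antimony, selenium), the
#' four land-use categories the wells are stratified by, and the two
#' sampling seasons.
#'
#' @return A character vector.
#' @export
gw_analytes <- function() GW_ANALYTES

#' @rdname gw_analytes
#' @export
gw_areas <- function() GW_AREAS

#' @rdname gw_analytes
#' @export
gw_seasons <- function() GW_SEASONS

#' Convert a concentration from ug/L to mg/L
#'
#' Monitoring data are carried in ug/L; the risk cascade consumes mg/L.
#' The conversion is exact division by 1000.
#'
#' @param x Numeric vector of concentrations in ug/L, all `>= 0`.
#' @return `x / 1000`, in mg/L.
#' @export
#' @examples
#' to_mg_per_L(24.5) # 0.0245
to_mg_per_L <- function(x) {
  if (!is.numeric(x)) {
    gw_abort("concentration must be numeric", "gw_validation_error")
  }
  if (any(x < 0, na.rm = TRUE)) {
    gw_abort("negative concentration is not a valid measurement", "gw_validation_error")
  }
  x / 1000
}

#' Cohort exposure parameters
#'
#' Daily drinking-water intake `DW` (L/day) and body weight `BW` (kg) for a
#' population group. Defaults follow the study design: adults drink 2.0 L/day
#' at 50 kg body weight, children 1.0 L/day at 20 kg.
#'
#' @param name Cohort label, `"adult"` or `"child"` for the defaults; any
#'   label is accepted when `DW` and `BW` are supplied.
#' @param DW Daily water intake in L/day (`> 0`).
#' @param BW Body weight in kg (`> 0`).
#' @return A one-row tibble with columns `cohort`, `DW`, `BW`.
#' @export
#' @examples
#' cohort_params("adult")
#' cohort_params("toddler", DW = 0.8, BW = 12)
cohort_params <- function(name, DW = NULL, BW = NULL) {
  defaults <- list(adult = c(DW = 2.0, BW = 50), child = c(DW = 1.0, BW = 20))
  if (is.null(DW) || is.null(BW)) {
    if (!name %in% names(defaults)) {
      gw_abort(
        sprintf("no default exposure parameters for cohort '%s'; supply DW and BW", name),
        "gw_validation_error"
      )
    }
    DW <- DW %||% defaults[[name]][["DW"]]
    BW <- BW %||% defaults[[name]][["BW"]]
  }
  if (DW <= 0 || BW <= 0) {
    gw_abort("cohort DW and BW must both be positive", "gw_validation_error")
  }
  tibble::tibble(cohort = name, DW = DW, BW = BW)
}

#' @rdname cohort_params
#' @export
default_cohorts <- function() {
  dplyr::bind_rows(cohort_params("adult"), cohort_params("child"))
}

#' Guideline limits and reference doses
#'
#' Loads a registry of named drinking-water limit sets (ug/L) and chronic
#' oral reference doses RfD (mg/kg/day) from a YAML file. The packaged
#' default carries the WHO limits (As 10, Sb 20, Se 40 ug/L) and the RfDs
#' used by the risk cascade (As 0.0003, Sb 0.0004, Se 0.005 mg/kg/day).
#'
#' @param path Path to a registry YAML; `NULL` loads the packaged default.
#' @return A list with elements `limits` (list of named numeric vectors,
#'   one per standard) and `rfd` (named numeric vector, mg/kg/day).
#' @export
#' @examples
#' reg <- load_guideline_registry()
#' reg$limits$WHO[["antimony"]] # 20
load_guideline_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "guidelines.yaml", package = "gwtrace", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$limits) || is.null(raw$rfd)) {
    gw_abort("registry must contain 'limits' and 'rfd' sections", "gw_schema_error")
  }
  limits <- lapply(raw$limits, function(l) unlist(l))
  rfd <- unlist(raw$rfd)
  vals <- c(unlist(limits, use.names = FALSE), rfd)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    gw_abort("all guideline limits and RfD values must be positive", "gw_validation_error")
  }
  list(limits = limits, rfd = rfd)
}

validate_records <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing)) {
    gw_abort(
      sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
      "gw_schema_error"
    )
  }
  bad_area <- setdiff(unique(records$area), GW_AREAS)
  if (length(bad_area)) {
    gw_abort(sprintf("unknown area label(s): %s", paste(bad_area, collapse = ", ")),
      "gw_validation_error")
  }
  bad_season <- setdiff(unique(records$season), GW_SEASONS)
  if (length(bad_season)) {
    gw_abort(sprintf("unknown season label(s): %s", paste(bad_season, collapse = ", ")),
      "gw_validation_error")
  }
  bad_analyte <- setdiff(unique(records$analyte), GW_ANALYTES)
  if (length(bad_analyte)) {
    gw_abort(sprintf("unknown analyte label(s): %s", paste(bad_analyte, collapse = ", ")),
      "gw_validation_error")
  }
  neg <- which(records$conc_ugL < 0 | !is.finite(records$conc_ugL))
  if (length(neg)) {
    gw_abort(
      sprintf("invalid concentration at row(s) %s", paste(utils::head(neg, 5), collapse = ", ")),
      "gw_validation_error"
    )
  }
  # one land-use area per well, constant across records
  n_area <- tapply(records$area, records$well_id, function(a) length(unique(a)))
  if (any(n_area > 1)) {
    gw_abort(
      sprintf("well(s) mapped to more than one area: %s",
        paste(names(n_area)[n_area > 1], collapse = ", ")),
      "gw_validation_error"
    )
  }
  records$nondetect <- records$conc_ugL == 0
  records
}

#' Read a long-format monitoring CSV
#'
#' Expects the schema `well_id,area,season,month_index,analyte,conc_ugL`
#' (UTF-8, header required, "." decimal). Concentrations are in ug/L; a
#' value of 0 or the token `ND` marks a non-detect, following the study's
#' convention of recording below-detection measurements as zero.
#'
#' @param path Path to the CSV file.
#' @return A tibble of monitoring records with a logical `nondetect` column
#'   appended; unknown area/season/analyte labels and negative
#'   concentrations are rejected with an error naming the offending rows.
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) {
    gw_abort(sprintf("no such file: %s", path), "gw_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing)) {
    gw_abort(
      sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
      "gw_schema_error"
    )
  }
  conc <- trimws(raw$conc_ugL)
  is_nd <- toupper(conc) == "ND"
  conc[is_nd] <- "0"
  conc_num <- suppressWarnings(as.numeric(conc))
  if (anyNA(conc_num)) {
    gw_abort(
      sprintf("unparseable concentration at row(s) %s",
        paste(utils::head(which(is.na(conc_num)), 5), collapse = ", ")),
      "gw_validation_error"
    )
  }
  records <- tibble::tibble(
    well_id = raw$well_id,
    area = raw$area,
    season = raw$season,
    month_index = suppressWarnings(as.integer(raw$month_index)),
    analyte = raw$analyte,
    conc_ugL = conc_num
  )
  validate_records(records)
}

#' Write a table to CSV at full precision
#'
#' Deterministic column order (as given), no row names, numbers at full
#' double precision so that a write/read cycle is the identity on the
#' documented schemas.
#'
#' @param rows A data frame or tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(rows, path) {
  ok <- tryCatch(
    {
      utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
      TRUE
    },
    error = function(e) FALSE,
    warning = function(w) FALSE
  )
  if (!ok) {
    gw_abort(sprintf("cannot write to: %s", path), "gw_io_error")
  }
  invisible(path)
}

#' Load the packaged 35-well study fixture
#'
#' The package ships per-well summary statistics transcribed from the
#' published tables of the 2016 Ibadan shallow-groundwater campaign:
#' overall per-well mean/SD/range and seasonal (wet/dry) per-well mean/SD
#' for arsenic, antimony and selenium across 35 wells (24 residential
#' GW1-GW24, 5 commercial GW25-GW29, 4 industrial GW30-GW33, 2 agricultural
#' GW34-GW35). Zeros are non-detects recorded as zero and are included in
#' all means. See `inst/extdata/PROVENANCE.md` for transcription notes.
#'
#' @return A tibble of well summaries with columns `well_id`, `area`,
#'   `analyte`, `scope` (`"overall"`, `"wet"` or `"dry"`), `mean`, `sd`,
#'   `min`, `max` (range columns are `NA` for seasonal scopes). Structural
#'   integrity (row counts, area sizes, `min <= mean <= max`) is verified on
#'   every load.
#' @export
#' @examples
#' fx <- load_study_fixture()
#' length(unique(fx$well_id)) # 35
load_study_fixture <- function() {
  p2 <- system.file("extdata", "table2_overall.csv", package = "gwtrace", mustWork = TRUE)
  p3 <- system.file("extdata", "table3_seasonal.csv", package = "gwtrace", mustWork = TRUE)
  overall <- tibble::as_tibble(utils::read.csv(p2, stringsAsFactors = FALSE))
  seasonal <- tibble::as_tibble(utils::read.csv(p3, stringsAsFactors = FALSE))
  overall$scope <- "overall"
  seasonal$scope <- seasonal$season
  seasonal$season <- NULL
  seasonal$min <- NA_real_
  seasonal$max <- NA_real_
  fx <- dplyr::bind_rows(overall, seasonal)
  fx <- fx[, c("well_id", "area", "analyte", "scope", "mean", "sd", "min", "max")]

  wells <- unique(fx$well_id)
  area_of <- tapply(fx$area, fx$well_id, function(a) unique(a))
  counts <- table(unlist(area_of))
  ok <- length(wells) == 35 &&
    nrow(overall) == 105 && nrow(seasonal) == 210 &&
    identical(as.integer(counts[GW_AREAS]), c(24L, 5L, 4L, 2L)) &&
    all(overall$min <= overall$mean + 1e-9) &&
    all(overall$mean <= overall$max + 1e-9) &&
    all(fx$sd >= 0, na.rm = TRUE) &&
    all(fx$mean >= 0)
  if (!ok) {
    gw_abort("packaged study fixture failed its integrity checks", "gw_integrity_error")
  }
  fx
}
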