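#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

# Controlled vocabularies for the survey data model.
TROPHIC_GROUPS <- c("predators", "herbivores", "algae")
REGIONS <- c("tropical", "warm_temperate", "cool_temperate")
EXPLOITATION_STATUSES <- c("early_reserve", "late_reserve", "always_fished", "newly_fished")
VALUE_KINDS <- c("density", "percent_cover")

SURVEY_COLS <- c("region", "location_id", "site_id", "transect_id", "year",
                 "trophic_group", "value", "value_kind")
LOCATION_COLS <- c("location_id", "latitude", "exploitation_status", "reserve_start_year")

#' Read a transect-level survey table
#'
#' Reads a long-format CSV with one row per transect-level trophic-group total
#' (columns `region, location_id, site_id, transect_id, year, trophic_group,
#' value, value_kind`) and validates it against the data model: values must be
#' non-negative, key combinations unique, labels drawn from the controlled
#' vocabularies, and percent cover may exceed 100 only in temperate regions,
#' where cover is measured from the benthos to the canopy in three dimensions.
#'
#' @param path Path to a `surveys.csv`-style file.
#' @return A tibble of survey records, one row per transect observation.
#' @export
read_survey_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_survey_records(raw)
}

#' Validate a survey record table against the data model
#'
#' @param records A data frame with the survey columns.
#' @return The records as a tibble, invisibly checked; errors name the
#'   offending column or rows.
#' @export
validate_survey_records <- function(records) {
  missing <- setdiff(SURVEY_COLS, names(records))
  if (length(missing) > 0) {
    stop("survey table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)[SURVEY_COLS]
  records$year <- as.integer(records$year)

  bad_group <- !records$trophic_group %in% TROPHIC_GROUPS
  if (any(bad_group)) {
    stop("unknown trophic_group in rows: ", head_rows(which(bad_group)), call. = FALSE)
  }
  bad_region <- !records$region %in% REGIONS
  if (any(bad_region)) {
    stop("unknown region in rows: ", head_rows(which(bad_region)), call. = FALSE)
  }
  bad_kind <- !records$value_kind %in% VALUE_KINDS
  if (any(bad_kind)) {
    stop("unknown value_kind in rows: ", head_rows(which(bad_kind)), call. = FALSE)
  }
  neg <- is.na(records$value) | records$value < 0
  if (any(neg)) {
    stop("negative or missing value in rows: ", head_rows(which(neg)), call. = FALSE)
  }
  # 2-D tropical cover is bounded at 100%; only the 3-D temperate measure may exceed it.
  over <- records$value_kind == "percent_cover" & records$value > 100 &
    records$region == "tropical"
  if (any(over)) {
    stop("tropical percent_cover above 100 in rows: ", head_rows(which(over)),
         call. = FALSE)
  }
  key <- paste(records$location_id, records$site_id, records$transect_id,
               records$year, records$trophic_group, sep = "\r")
  if (anyDuplicated(key) > 0) {
    stop("duplicate (location, site, transect, year, trophic_group) keys in rows: ",
         head_rows(which(duplicated(key))), call. = FALSE)
  }
  records
}

head_rows <- function(idx, n = 5) {
  shown <- paste(utils::head(idx, n), collapse = ", ")
  if (length(idx) > n) shown <- paste0(shown, ", ... (", length(idx), " total)")
  shown
}

#' Read a location metadata table
#'
#' Reads `locations.csv` (columns `location_id, latitude, exploitation_status,
#' reserve_start_year`, optionally `analysis_start_year`). Latitude is stored
#' signed, negative south, so the equator sits at zero. When
#' `analysis_start_year` is absent it is resolved from the exploitation
#' category: reserve locations start their trend analysis at the reserve
#' implementation year; fished locations carry no start year unless one was
#' supplied (the matched start year of their geographic area's reserve).
#'
#' @param path Path to the metadata CSV.
#' @return A tibble with one row per location, including `analysis_start_year`.
#' @export
read_location_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_location_meta(raw)
}

#' Validate location metadata
#'
#' @param meta Data frame of location metadata.
#' @return A validated tibble with `analysis_start_year` resolved.
#' @export
validate_location_meta <- function(meta) {
  missing <- setdiff(LOCATION_COLS, names(meta))
  if (length(missing) > 0) {
    stop("location table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- tibble::as_tibble(meta)
  if (anyDuplicated(meta$location_id) > 0) {
    stop("duplicate location_id in metadata", call. = FALSE)
  }
  if (any(!meta$exploitation_status %in% EXPLOITATION_STATUSES)) {
    stop("exploitation_status must be one of: ",
         paste(EXPLOITATION_STATUSES, collapse = ", "), call. = FALSE)
  }
  if (any(meta$latitude < -90 | meta$latitude > 90)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  is_reserve <- meta$exploitation_status %in% c("early_reserve", "late_reserve")
  if (any(is_reserve & is.na(meta$reserve_start_year))) {
    stop("reserve_start_year required for early_reserve and late_reserve locations",
         call. = FALSE)
  }
  if (!"analysis_start_year" %in% names(meta)) {
    meta$analysis_start_year <- ifelse(is_reserve, meta$reserve_start_year, NA_real_)
  }
  meta$analysis_start_year <- as.integer(round(meta$analysis_start_year))
  meta$reserve_start_year <- as.integer(round(meta$reserve_start_year))
  meta
}

#' Write survey records / location metadata to CSV
#'
#' UTF-8 CSV with a header row; missing numeric values are written as empty
#' fields. Reading the file back reproduces the table exactly.
#'
#' @param x Table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x)[SURVEY_COLS], path, na = "")
  invisible(path)
}

#' @rdname write_survey_table
#' @export
write_location_table <- function(x, path) {
  cols <- intersect(c(LOCATION_COLS, "analysis_start_year"), names(x))
  readr::write_csv(tibble::as_tibble(x)[cols], path, na = "")
  invisible(path)
}

#' Pre-analysis quality report for a survey dataset
#'
#' Checks every location x trophic-group series against the analysis
#' requirements: at least 3 yearly time points, at least 12 surveys (unique
#' year-by-site combinations), non-constant annual means, and notes uneven
#' site sampling across years (which rules out the AR-1 trend variant but not
#' the ordinary one). Locations are reported, never silently excluded.
#'
#' @param records Survey records (validated).
#' @param meta Location metadata; every location in `records` must appear.
#' @param start_year_applied If `FALSE` (default) the report first truncates
#'   series at each location's `analysis_start_year` via [apply_start_year()].
#' @return A `validation_report`: list with `series` (per-series tibble of
#'   counts and flags) and `pass` (logical, all series pass).
#' @export
validate_dataset <- function(records, meta, start_year_applied = FALSE) {
  records <- validate_survey_records(records)
  meta <- validate_location_meta(meta)
  orphan <- setdiff(unique(records$location_id), meta$location_id)
  if (length(orphan) > 0) {
    stop("locations present in records but absent from metadata: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  if (!start_year_applied) records <- apply_start_year(records, meta)

  site_year <- site_year_means(records)
  annual <- location_year_series(site_year)

  per_series <- annual |>
    dplyr::group_by(.data$location_id, .data$trophic_group) |>
    dplyr::summarise(
      n_years = dplyr::n_distinct(.data$year),
      constant_series = stats::sd(.data$raw_mean) == 0,
      .groups = "drop"
    )
  surveys <- site_year |>
    dplyr::group_by(.data$location_id, .data$trophic_group) |>
    dplyr::summarise(
      n_surveys = dplyr::n_distinct(paste(.data$site_id, .data$year)),
      uneven_sites = dplyr::n_distinct(
        tapply(.data$site_id, .data$year, function(s) paste(sort(unique(s)), collapse = ";"))
      ) > 1,
      .groups = "drop"
    )
  series <- dplyr::left_join(per_series, surveys,
                             by = c("location_id", "trophic_group")) |>
    dplyr::mutate(
      too_short = .data$n_years < 3,
      too_few_surveys = .data$n_surveys < 12,
      pass = !.data$too_short & !.data$too_few_surveys & !.data$constant_series
    )
  structure(list(series = series, pass = all(series$pass)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  n_fail <- sum(!x$series$pass)
  cat("Survey dataset validation: ", nrow(x$series), " series, ",
      n_fail, " failing\n", sep = "")
  if (n_fail > 0) print(dplyr::filter(x$series, !.data$pass), n = 20)
  invisible(x)
}
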