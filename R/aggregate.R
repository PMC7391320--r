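#' Truncate records at each location's analysis start year
#'
#' Trend analyses at reserve locations start at the year the reserve was
#' implemented; fished locations in the same geographic area use the matched
#' reserve's start year (supplied as `analysis_start_year` in the metadata) to
#' control for shared temporal factors. Locations without a start year keep
#' all their records.
#'
#' @param records Survey records.
#' @param meta Location metadata with `analysis_start_year`.
#' @return The records with years before the start year removed.
#' @export
apply_start_year <- function(records, meta) {
  start <- meta$analysis_start_year[match(records$location_id, meta$location_id)]
  keep <- is.na(start) | records$year >= start
  records[keep, , drop = FALSE]
}

#' Mean trophic-group value per site and year
#'
#' Transect totals are averaged across transects within each site; site is the
#' unit of replication because contiguous transects within a site are not
#' independent.
#'
#' @param records Survey records.
#' @return Tibble with one row per (location, site, year, trophic group) and
#'   the transect mean `mean_value`.
#' @export
site_year_means <- function(records) {
  records |>
    dplyr::group_by(.data$region, .data$location_id, .data$site_id,
                    .data$year, .data$trophic_group) |>
    dplyr::summarise(mean_value = mean(.data$value),
                     n_transects = dplyr::n(), .groups = "drop")
}

#' Annual location-level series from site means
#'
#' Unweighted mean across the sites surveyed in each year; years with no
#' surveyed site are simply absent (no imputation).
#'
#' @param site_year Output of [site_year_means()].
#' @return Tibble with one row per (location, trophic group, year): `raw_mean`
#'   and the number of contributing sites, ordered by year within series.
#' @export
location_year_series <- function(site_year) {
  site_year |>
    dplyr::group_by(.data$region, .data$location_id, .data$trophic_group,
                    .data$year) |>
    dplyr::summarise(raw_mean = mean(.data$mean_value),
                     n_sites = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$location_id, .data$trophic_group, .data$year)
}

#' Standardize one annual series to mean zero, unit standard deviation
#'
#' Density metrics differ between monitoring programs and trophic groups, so
#' each location x group time series is rescaled to a common currency before
#' trend fitting. Uses the sample (n-1) standard deviation of the annual
#' location-level means; the same constants are applied to site-level values
#' so that regression replicates live on the same scale.
#'
#' @param raw_means Numeric vector of annual means (length >= 3).
#' @return List with `std` (standardized values), `center`, `scale`.
#' @export
standardize_series <- function(raw_means) {
  if (length(raw_means) < 3) {
    stop("series has fewer than 3 yearly points", call. = FALSE)
  }
  s <- stats::sd(raw_means)
  if (!is.finite(s) || s == 0) {
    stop(constant_series_error())
  }
  m <- mean(raw_means)
  list(std = (raw_means - m) / s, center = m, scale = s)
}

constant_series_error <- function() {
  structure(class = c("reeftrends_constant_series", "error", "condition"),
            list(message = "constant series: standardization impossible (sd = 0)",
                 call = NULL))
}

#' Build standardized location series and site-level replicates
#'
#' Runs the full aggregation chain: start-year truncation, transect-to-site
#' means, site-to-location annual means, and per-series standardization. The
#' standardization constants come from the location-level annual means and are
#' also applied to the site-year means, which are the replicate points used in
#' trend regressions.
#'
#' Constant series (sd = 0 across years) cannot be standardized; they are
#' returned with `constant = TRUE` and `std_mean = NA`, and downstream trend
#' fits report them as non-significant.
#'
#' @param records Survey records.
#' @param meta Location metadata (used for the start-year rule); `NULL` skips
#'   truncation.
#' @return List with `series` (annual location series: `raw_mean`, `std_mean`,
#'   `n_sites`, `constant`) and `site_repl` (standardized site-year replicate
#'   points: `std_value`).
#' @export
build_location_series <- function(records, meta = NULL) {
  if (!is.null(meta)) records <- apply_start_year(records, meta)
  site_year <- site_year_means(records)
  annual <- location_year_series(site_year)

  consts <- annual |>
    dplyr::group_by(.data$region, .data$location_id, .data$trophic_group) |>
    dplyr::summarise(center = mean(.data$raw_mean),
                     scale = stats::sd(.data$raw_mean),
                     n_years = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(constant = .data$scale == 0)

  series <- annual |>
    dplyr::left_join(consts, by = c("region", "location_id", "trophic_group")) |>
    dplyr::mutate(std_mean = ifelse(.data$constant, NA_real_,
                                    (.data$raw_mean - .data$center) / .data$scale))

  site_repl <- site_year |>
    dplyr::left_join(consts, by = c("region", "location_id", "trophic_group")) |>
    dplyr::mutate(std_value = ifelse(.data$constant, NA_real_,
                                     (.data$mean_value - .data$center) / .data$scale)) |>
    dplyr::select(dplyr::all_of(c("region", "location_id", "site_id", "year",
                                  "trophic_group", "std_value", "constant")))

  list(series = series, site_repl = site_repl)
}
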