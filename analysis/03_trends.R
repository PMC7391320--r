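#!/usr/bin/env Rscript
# Stage 3: per-series trend detection and adjacent-pair correlations.
#
# Each standardized series is tested for a linear time trend by OLS on the
# site-year replicates (two-sided t test, alpha = .05) and, where site-level
# sampling is even across years, by the conservative AR(1) variant. Pearson
# coefficients between adjacent trophic groups' annual series diagnose the
# forcing direction (positive ~ bottom-up, negative ~ top-down) and are
# carried to Fisher z with inverse-variance weights n_years - 3.

suppressMessages(library(reeftrends))

site_repl <- readr::read_csv("results/data/site_replicates.csv",
                             show_col_types = FALSE)
series <- readr::read_csv("results/data/series.csv", show_col_types = FALSE)
meta <- read_location_table("results/data/locations.csv")
meta$region <- region_from_latitude(meta$latitude)
series <- dplyr::left_join(series,
                           dplyr::select(meta, location_id, region),
                           by = "location_id")
series$constant <- is.na(series$std_mean)

agg <- list(series = series, site_repl = site_repl)
trends <- fit_trends(agg, alpha = 0.05, method = "both")
pairs <- pair_correlations(series)

readr::write_csv(dplyr::select(trends, location_id, trophic_group, method,
                               slope, se, t, p, r2, n_points, n_years,
                               direction, rho, applicable),
                 "results/trends.csv", na = "")
readr::write_csv(dplyr::select(pairs, location_id, pair, r, n_years, z,
                               z_var, weight),
                 "results/correlations.csv", na = "")

ols <- dplyr::filter(trends, method == "ols")
cat("Significant trends (OLS, alpha = .05) by group:\n")
print(with(ols, table(trophic_group, direction)))
both <- dplyr::filter(trends, applicable, !constant) |>
  tidyr::pivot_wider(id_cols = c(location_id, trophic_group),
                     names_from = method, values_from = slope)
cat(sprintf("OLS / AR-1 slope-sign agreement: %.1f%% of %d series\n",
            100 * mean(sign(both$ols) == sign(both$ar1)), nrow(both)))
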