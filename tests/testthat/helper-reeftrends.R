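# Shared fixtures, built in code.

.cache <- new.env(parent = emptyenv())

# The study-scale default simulation + full pipeline (both trend methods),
# shared by several tests; computed once per test run.
default_run_cached <- function() {
  if (is.null(.cache$run)) {
    .cache$run <- suppressWarnings(
      run_pipeline(default_sim_config(seed = 1), method = "both"))
  }
  .cache$run
}

# A tiny hand-written survey table: 2 locations x 3 groups, 3 sites, 4 years,
# 2 transects. Values increase with year for predators so trends are real.
tiny_records <- function() {
  grid <- expand.grid(site = 1:3, transect = 1:2, year = 2000:2003,
                      group = c("predators", "herbivores", "algae"),
                      loc = c("A", "B"), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    region = ifelse(grid$loc == "A", "tropical", "cool_temperate"),
    location_id = grid$loc,
    site_id = paste0(grid$loc, "_s", grid$site),
    transect_id = paste0(grid$loc, "_s", grid$site, "_t", grid$transect),
    year = grid$year,
    trophic_group = grid$group,
    value = 10 + (grid$year - 2000) * (grid$group == "predators") +
      grid$site + 0.5 * grid$transect,
    value_kind = ifelse(grid$group == "algae", "percent_cover", "density")
  )
}

tiny_meta <- function() {
  tibble::tibble(
    location_id = c("A", "B"),
    latitude = c(-16, -42),
    exploitation_status = c("early_reserve", "always_fished"),
    reserve_start_year = c(2000L, NA_integer_),
    analysis_start_year = c(2000L, 2000L)
  )
}

# One-row trend results for classification tests.
fake_trend <- function(group, direction, p = if (direction == "none") 0.2 else 0.01) {
  slope <- switch(direction, increasing = 0.1, decreasing = -0.1, none = 0.01)
  tibble::tibble(location_id = "X", trophic_group = group, slope = slope,
                 se = 0.01, t = slope / 0.01, p = p, r2 = 0.5, n_points = 20,
                 n_years = 10, direction = direction, method = "ols",
                 exact_fit = FALSE, constant = FALSE, rho = NA_real_,
                 applicable = TRUE, converged = TRUE)
}

fake_location_trends <- function(pred, herb, alg) {
  dplyr::bind_rows(fake_trend("predators", pred),
                   fake_trend("herbivores", herb),
                   fake_trend("algae", alg))
}

# Classification table with given counts of alternating / other
# predator-significant / non-significant locations.
fake_classifications <- function(n_alt, n_sig_other, n_nonsig, region = "tropical") {
  n <- n_alt + n_sig_other + n_nonsig
  tibble::tibble(
    region = region,
    location_id = sprintf("C%03d", seq_len(n)),
    predator_direction = rep(c("increasing", "increasing", "none"),
                             times = c(n_alt, n_sig_other, n_nonsig)),
    herbivore_direction = rep(c("decreasing", "none", "none"),
                              times = c(n_alt, n_sig_other, n_nonsig)),
    algae_direction = rep(c("increasing", "none", "none"),
                          times = c(n_alt, n_sig_other, n_nonsig)),
    predator_significant = rep(c(TRUE, TRUE, FALSE),
                               times = c(n_alt, n_sig_other, n_nonsig)),
    alternating = rep(c(TRUE, FALSE, FALSE), times = c(n_alt, n_sig_other, n_nonsig)),
    partial_alternating = FALSE,
    pattern = "P+H-A+"
  )
}

final_terms_of <- function(st) attr(stats::terms(st$final$fit), "term.labels")

# Config with iid observation noise only (no year or site variance): the
# setting in which the site-replicate OLS t test is exactly calibrated.
iid_null_config <- function(n_locations, seed) {
  sim_config(n_locations = n_locations, years_range = c(5, 5),
             n_sites_range = c(3, 3), n_transects = 1, rho = 0,
             sigma_year = 0, sigma_site = 0, sigma_obs = 0.3,
             regimes = regime_spec("null"), seed = seed)
}
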