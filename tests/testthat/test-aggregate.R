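test_that("start-year rule truncates reserve and matched fished locations", {
  rec <- tibble::tibble(
    region = "cool_temperate",
    location_id = rep(c("R", "F", "U"), each = 11),
    site_id = "s1", transect_id = "t1",
    year = rep(1990:2000, 3),
    trophic_group = "predators",
    value = 1, value_kind = "density"
  )
  rec$transect_id <- paste0(rec$location_id, "_t1")
  rec$site_id <- paste0(rec$location_id, "_s1")
  meta <- tibble::tibble(
    location_id = c("R", "F", "U"),
    latitude = -42,
    exploitation_status = c("early_reserve", "always_fished", "always_fished"),
    reserve_start_year = c(1992L, NA, NA),
    analysis_start_year = c(1992L, 1992L, NA)   # F matched to R's start; U unmatched
  )
  out <- apply_start_year(rec, meta)
  expect_equal(sort(unique(out$year[out$location_id == "R"])), 1992:2000)
  expect_equal(sort(unique(out$year[out$location_id == "F"])), 1992:2000)
  expect_equal(sort(unique(out$year[out$location_id == "U"])), 1990:2000)
})

test_that("aggregation means follow the transect -> site -> location hierarchy", {
  rec <- tiny_records()
  idx <- which(rec$location_id == rec$location_id[1] &
                 rec$site_id == rec$site_id[1] & rec$year == rec$year[1] &
                 rec$trophic_group == rec$trophic_group[1])
  rec$value[idx] <- c(4, 6)   # same site/year/group, two transects
  sy <- site_year_means(rec)
  expect_equal(sy$mean_value[sy$site_id == rec$site_id[1] & sy$year == rec$year[1] &
                               sy$trophic_group == rec$trophic_group[1]], 5)

  sy2 <- tibble::tibble(region = "tropical", location_id = "L",
                        site_id = c("s1", "s2"), year = 2000,
                        trophic_group = "predators", mean_value = c(5, 7),
                        n_transects = 1)
  expect_equal(location_year_series(sy2)$raw_mean, 6)

  # sites present vary by year: each year averages only its observed sites
  sy3 <- dplyr::bind_rows(sy2, sy2[1, ] |> dplyr::mutate(year = 2001, mean_value = 9))
  ann <- location_year_series(sy3)
  expect_equal(ann$raw_mean[ann$year == 2001], 9)
  expect_equal(ann$n_sites, c(2L, 1L))

  # permutation invariance over input rows
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(location_year_series(site_year_means(shuffled)),
               location_year_series(site_year_means(rec)))
})

test_that("standardization centers and scales with the sample sd and is idempotent", {
  z <- standardize_series(c(2, 4, 6))
  expect_equal(z$std, c(-1, 0, 1))
  expect_equal(z$center, 4)
  expect_equal(z$scale, 2)
  expect_equal(standardize_series(z$std)$std, z$std, tolerance = 1e-12)
  expect_error(standardize_series(c(5, 5, 5)), class = "reeftrends_constant_series")
  expect_error(standardize_series(c(1, 2)), "fewer than 3")
})

test_that("every emitted standardized series has mean 0 and sd 1", {
  sim <- simulate_dataset(sim_config(n_locations = 8, seed = 9))
  agg <- build_location_series(sim$records, sim$meta)
  chk <- agg$series |>
    dplyr::group_by(location_id, trophic_group) |>
    dplyr::summarise(m = mean(std_mean), s = stats::sd(std_mean), .groups = "drop")
  expect_true(all(abs(chk$m) < 1e-10))
  expect_true(all(abs(chk$s - 1) < 1e-10))
})

test_that("correlations and trend p-values are invariant to standardization", {
  sim <- simulate_dataset(sim_config(n_locations = 4, seed = 30,
                                     regimes = regime_spec("independent", slope_sd = 0.1)))
  agg <- build_location_series(sim$records, sim$meta)
  raw_series <- agg$series |>
    dplyr::group_by(location_id, trophic_group) |>
    dplyr::arrange(year, .by_group = TRUE)

  for (loc in unique(agg$series$location_id)) {
    d <- dplyr::filter(agg$series, location_id == loc)
    p <- dplyr::filter(d, trophic_group == "predators")
    h <- dplyr::filter(d, trophic_group == "herbivores")
    expect_equal(stats::cor(p$raw_mean, h$raw_mean),
                 stats::cor(p$std_mean, h$std_mean), tolerance = 1e-10)
  }
  # trend t and p identical on raw vs standardized site replicates
  sy <- site_year_means(apply_start_year(sim$records, sim$meta))
  one <- dplyr::filter(sy, location_id == sim$meta$location_id[1],
                       trophic_group == "algae")
  one_std <- dplyr::filter(agg$site_repl, location_id == sim$meta$location_id[1],
                           trophic_group == "algae")
  f_raw <- fit_linear_trend(one$year, one$mean_value)
  f_std <- fit_linear_trend(one_std$year, one_std$std_value)
  expect_equal(f_raw$t, f_std$t, tolerance = 1e-10)
  expect_equal(f_raw$p, f_std$p, tolerance = 1e-10)
})
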