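test_that("weighted regression reduces to OLS and interpolates saturated designs", {
  d <- data.frame(x = c(1, 2, 3), y = c(1, 2, 3))
  f <- suppressWarnings(weighted_regression(y ~ x, d))  # exact line: perfect fit
  expect_equal(unname(coef(f$fit)), c(0, 1), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  d2 <- data.frame(x = c(0, 1), y = c(3, 7))
  f2 <- weighted_regression(y ~ x, d2, weights = c(0.3, 9))
  expect_equal(unname(fitted(f2$fit)), c(3, 7), tolerance = 1e-12)

  set.seed(2)
  d3 <- data.frame(x = rnorm(12), y = rnorm(12))
  f3 <- weighted_regression(y ~ x, d3, weights = rep(2, 12))
  expect_equal(coef(f3$fit), coef(lm(y ~ x, d3)), tolerance = 1e-10)
})

test_that("weighted regression matches the closed-form weighted normal equations", {
  set.seed(3)
  d <- data.frame(x = c(0.2, 1.1, 2.7, 3.3, 4.8), y = c(1.9, 2.4, 2.2, 4.1, 4.4))
  w <- c(7, 1, 4, 2, 9)
  f <- weighted_regression(y ~ x, d, w)
  X <- cbind(1, d$x)
  beta <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% d$y)
  expect_equal(unname(coef(f$fit)), as.numeric(beta), tolerance = 1e-10)

  # rank deficiency is reported with the collinear term named
  d$x2 <- 2 * d$x
  expect_error(weighted_regression(y ~ x + x2, d, w), "collinear.*x2")
})

test_that("zero-weight points are excluded from the fit and counted", {
  d <- data.frame(x = 1:6, y = c(1, 2, 3, 4, 5, 60))
  w <- c(1, 1, 1, 1, 1, 0)
  f <- suppressWarnings(weighted_regression(y ~ x, d, w))  # subset is an exact line
  expect_equal(f$n_used, 5L)
  expect_equal(f$n_excluded, 1L)
  expect_equal(unname(coef(f$fit)), unname(coef(lm(y ~ x, d[1:5, ]))),
               tolerance = 1e-12)
})

test_that("logit model closed forms: balanced groups, intercept-only MLE, separation", {
  d <- data.frame(alternating = c(0, 1, 0, 1), x = c(0, 0, 1, 1))
  f <- fit_binomial_logit(alternating ~ x, d)
  expect_equal(unname(coef(f$fit)), c(0, 0), tolerance = 1e-8)

  # 4 successes of 24: intercept = logit(4/24) = log(4/20)
  d2 <- data.frame(alternating = rep(c(1, 0), c(4, 20)))
  f2 <- fit_binomial_logit(alternating ~ 1, d2)
  expect_equal(unname(coef(f2$fit)), log(4 / 20), tolerance = 1e-8)
  expect_equal(round(unname(coef(f2$fit)), 4), -1.6094)
  expect_equal(f2$aic, -2 * as.numeric(logLik(f2$fit)) + 2, tolerance = 1e-10)

  d3 <- data.frame(alternating = c(0, 0, 1, 1), x = c(0, 0, 1, 1))
  expect_warning(f3 <- fit_binomial_logit(alternating ~ x, d3), "separation")
  expect_true(f3$separation_flag)

  expect_error(fit_binomial_logit(alternating ~ 1,
                                  data.frame(alternating = rep(1, 5))),
               "degenerate response")
})

test_that("the IRLS solution satisfies the score equations", {
  set.seed(14)
  n <- 150
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  eta <- -0.5 + 1.2 * d$x1
  d$alternating <- rbinom(n, 1, plogis(eta))
  f <- fit_binomial_logit(alternating ~ x1 + x2, d)
  X <- model.matrix(f$fit)
  score <- t(X) %*% (d$alternating - fitted(f$fit))
  expect_true(all(abs(score) < 1e-8))
  expect_true(all(fitted(f$fit) > 0 & fitted(f$fit) < 1))
})

test_that("backward stepwise removes a null factor block and keeps a real slope", {
  set.seed(8)
  n <- 80
  d <- data.frame(
    latitude = runif(n, -43, -14),
    exploitation_status = sample(c("early_reserve", "late_reserve",
                                   "always_fished", "newly_fished"),
                                 n, replace = TRUE)
  )
  d$alternating <- rbinom(n, 1, plogis(-8 - 0.25 * d$latitude))  # latitude only
  full <- suppressWarnings(fit_binomial_logit(
    alternating ~ latitude + exploitation_status, d))
  st <- backward_stepwise(full)
  expect_identical(final_terms_of(st), "latitude")
  expect_true("exploitation_status" %in% st$trace$dropped)
  expect_true(all(st$trace$drop_p > 0.05, na.rm = TRUE))

  # all terms significant: stepwise is a no-op with a single trace row
  d2 <- data.frame(x = rnorm(200))
  d2$alternating <- rbinom(200, 1, plogis(2 * d2$x))
  st2 <- backward_stepwise(fit_binomial_logit(alternating ~ x, d2))
  expect_identical(nrow(st2$trace), 1L)
  expect_identical(final_terms_of(st2), "x")

  # intercept-only endpoint is valid
  d3 <- data.frame(x = rnorm(60), alternating = rbinom(60, 1, 0.4))
  st3 <- backward_stepwise(fit_binomial_logit(alternating ~ x, d3))
  expect_length(final_terms_of(st3), 0)
})

test_that("stepwise keeps the informative covariate among noise covariates (Monte-Carlo)", {
  set.seed(77)
  keep_info <- logical(100)
  n_noise_dropped <- integer(100)
  for (i in 1:100) {
    n <- 200
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
    d$alternating <- rbinom(n, 1, plogis(2 * d$x1))
    st <- backward_stepwise(suppressWarnings(
      fit_binomial_logit(alternating ~ x1 + x2 + x3 + x4, d)))
    terms <- final_terms_of(st)
    keep_info[i] <- "x1" %in% terms
    n_noise_dropped[i] <- 3 - length(intersect(c("x2", "x3", "x4"), terms))
  }
  expect_gt(mean(keep_info), 0.5)
  expect_gt(mean(n_noise_dropped >= 2), 0.5)
})

test_that("Fisher-z latitude model applies inverse-variance weights and the 3-year toggle", {
  pairs <- tibble::tibble(
    region = "tropical", location_id = sprintf("L%02d", 1:6),
    pair = "herbivore_algae",
    r = c(0.5, 0.4, -0.2, 0.1, 0.3, -0.4),
    n_years = c(10, 8, 6, 3, 12, 7), undefined = FALSE
  )
  pairs <- fisher_transform(pairs)
  meta <- tibble::tibble(location_id = pairs$location_id,
                         latitude = seq(-40, -15, length.out = 6))
  f <- fisherz_latitude_model(pairs, meta)
  expect_equal(f$n_used, 5L)       # the 3-year pair carries weight 0
  expect_equal(f$n_excluded, 1L)
  f3 <- fisherz_latitude_model(pairs, meta, min_years_weighted = 3)
  expect_equal(f3$n_used, 6L)

  # oracle: weighted normal equations on the same points
  d <- dplyr::left_join(pairs, meta, by = "location_id") |>
    dplyr::filter(weight > 0)
  X <- cbind(1, d$latitude)
  beta <- solve(t(X) %*% diag(d$weight) %*% X, t(X) %*% diag(d$weight) %*% d$z)
  expect_equal(unname(coef(f$fit)), as.numeric(beta), tolerance = 1e-10)
})

test_that("trend-covariate models handle flat trends and degenerate categories", {
  trends <- dplyr::bind_rows(lapply(sprintf("L%02d", 1:10), function(l) {
    t <- fake_location_trends("increasing", "increasing", "increasing")
    t$location_id <- l
    t$slope <- 0.08          # identical trends everywhere
    t
  }))
  meta <- tibble::tibble(location_id = sprintf("L%02d", 1:10),
                         latitude = seq(-43, -15, length.out = 10),
                         exploitation_status = "always_fished")
  wrns <- capture_warnings(out <- trend_vs_covariate_models(trends, meta))
  expect_true(any(grepl("single exploitation category", wrns)))
  lat_fit <- out$predators$latitude$final
  lat_coef <- lat_fit$coefficients
  slope_est <- lat_coef$estimate[lat_coef$term == "latitude"]
  expect_true(length(slope_est) == 0 || abs(slope_est) < 1e-10)
  expect_null(out$predators$exploitation)
  expect_equal(out$predators$category_means$mean_slope, 0.08, tolerance = 1e-12)
})
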