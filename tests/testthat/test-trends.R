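test_that("OLS trend matches the hand-computed example and the closed-form df=2 p", {
  f <- fit_linear_trend(1:4, c(1, 2, 2, 3))
  expect_equal(f$slope, 0.6, tolerance = 1e-12)
  expect_equal(f$se, sqrt(0.1 / 5), tolerance = 1e-12)
  expect_equal(f$t, 0.6 / sqrt(0.1 / 5), tolerance = 1e-12)
  # for df = 2, P(T <= t) = 1/2 + t / (2 * sqrt(t^2 + 2))
  p_closed <- 2 * (1 - (0.5 + f$t / (2 * sqrt(f$t^2 + 2))))
  expect_equal(f$p, p_closed, tolerance = 1e-10)
  expect_equal(round(f$p, 4), 0.0513)
  expect_identical(f$direction, "none")   # just above alpha = .05
  expect_identical(f$n_points, 4L)
})

test_that("degenerate trend inputs are handled: constant, exact fit, one year", {
  cst <- fit_linear_trend(1:5, rep(2, 5))
  expect_equal(cst$slope, 0)
  expect_identical(cst$direction, "none")
  expect_true(cst$constant)

  ex <- fit_linear_trend(1:5, 1:5)
  expect_equal(ex$slope, 1)
  expect_equal(ex$r2, 1)
  expect_true(ex$exact_fit)
  expect_equal(ex$p, 0)
  expect_identical(ex$direction, "increasing")

  expect_error(fit_linear_trend(rep(2000, 4), rnorm(4)), "distinct years")
})

test_that("OLS equals the closed-form normal-equations solution on random instances", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    yrs <- sort(sample(1990:2015, n, replace = TRUE))
    if (dplyr::n_distinct(yrs) < 3) next
    y <- rnorm(n)
    f <- fit_linear_trend(yrs, y)
    X <- cbind(1, yrs - mean(yrs))
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(f$slope, beta[2], tolerance = 1e-10)
  }
})

test_that("AR-1 fit agrees with OLS when the year effects are uncorrelated", {
  set.seed(11)
  res <- t(replicate(40, {
    T <- 15; S <- 3; sy <- 0.3; so <- 0.15
    u <- rnorm(T, 0, sy)
    yrs <- rep(1:T, each = S)
    sites <- rep(sprintf("s%d", 1:S), T)
    vals <- u[yrs] + rnorm(T * S, 0, so)
    a <- fit_ar1_trend(yrs, vals, sites)
    o <- fit_linear_trend(yrs, vals)
    c(rho = a$rho, dslope = abs(a$slope - o$slope))
  }))
  expect_lt(mean(res[, "rho"]), 0.25)
  expect_lt(stats::median(res[, "rho"]), 0.1)
  expect_true(all(res[, "dslope"] < 0.05))
})

test_that("AR-1 REML recovers the year-effect autocorrelation (Monte-Carlo)", {
  set.seed(42)
  rhohat <- replicate(200, {
    T <- 19; S <- 3; rho <- 0.6; sy <- 0.3; so <- 0.15
    z <- rnorm(T)
    u <- numeric(T)
    u[1] <- sy * z[1]
    for (t in 2:T) u[t] <- rho * u[t - 1] + sy * sqrt(1 - rho^2) * z[t]
    yrs <- rep(1:T, each = S)
    sites <- rep(sprintf("s%d", 1:S), T)
    vals <- u[yrs] + rnorm(T * S, 0, so)
    fit_ar1_trend(yrs, vals, sites)$rho
  })
  expect_lt(abs(mean(rhohat) - 0.6), 0.1)
})

test_that("AR-1 model is inapplicable under uneven site-level sampling", {
  T <- 8; S <- 3
  yrs <- rep(1:T, each = S)
  sites <- rep(sprintf("s%d", 1:S), T)
  vals <- rnorm(T * S)
  drop_one <- !(yrs == 4 & sites == "s2")   # one site missing in one year
  out <- fit_ar1_trend(yrs[drop_one], vals[drop_one], sites[drop_one])
  expect_false(out$applicable)
  expect_true(is.na(out$slope))
})

test_that("pair correlations follow the Pearson definition on common years", {
  expect_equal(pair_correlation(1:4, 1:4, 1:4, 1:4)$r, 1)
  expect_equal(pair_correlation(1:4, 1:4, 1:4, -(1:4))$r, -1)
  expect_equal(pair_correlation(1:4, c(1, 2, 3, 4), 1:4, c(2, 1, 4, 3))$r, 0.6,
               tolerance = 1e-12)
  # only overlapping years enter
  # only overlapping years (2-5) enter, values matched by year
  expect_equal(pair_correlation(1:5, c(1, 2, 3, 4, 9), 2:6, c(9, 2, 1, 4, 3))$r,
               stats::cor(c(2, 3, 4, 9), c(9, 2, 1, 4)), tolerance = 1e-12)
  expect_error(pair_correlation(1:2, 1:2, 1:2, 1:2), "common years")
  und <- pair_correlation(1:4, rep(1, 4), 1:4, 1:4)
  expect_true(und$undefined)
  expect_true(is.na(und$r))
})

test_that("Fisher transform matches the closed form, weights, and boundaries", {
  pc <- tibble::tibble(r = c(0, 0.6, 0.2, 1), n_years = c(10, 10, 3, 8))
  ft <- fisher_transform(pc)
  expect_equal(ft$z[1], 0)
  expect_equal(ft$z[2], 0.5 * log((1 + 0.6) / (1 - 0.6)), tolerance = 1e-12)
  expect_equal(round(ft$z[2], 4), 0.6931)
  expect_equal(ft$z_var[2], 1 / 7)
  expect_equal(ft$weight[2], 7)
  # 3-year pair: weight 0, undefined variance
  expect_equal(ft$weight[3], 0)
  expect_true(is.na(ft$z_var[3]))
  # |r| = 1: infinite z flagged and excluded from weighting
  expect_true(ft$infinite_z[4])
  expect_equal(ft$weight[4], 0)
  # atanh/tanh round trip
  r <- seq(-0.99, 0.99, by = 0.03)
  expect_true(all(abs(tanh(atanh(r)) - r) < 1e-12))
})
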