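#' Ordinary least-squares trend of a standardized series
#'
#' Regresses the standardized values on (internally centered) calendar year by
#' OLS and tests the slope with a two-sided t test on `n - 2` degrees of
#' freedom. The replicate points are normally the standardized site-year
#' means, so the test uses site as the unit of replication. A trend direction
#' is assigned only when the slope is significant at `alpha`.
#'
#' @param years Numeric vector of calendar years (>= 3 distinct values).
#' @param values Standardized values, same length.
#' @param alpha Two-sided significance level (default 0.05, uncorrected).
#' @return One-row tibble: `slope`, `se`, `t`, `p`, `r2`, `n_points`,
#'   `n_years`, `direction` (`increasing`/`decreasing`/`none`), `method`,
#'   `exact_fit`, `constant`.
#' @export
fit_linear_trend <- function(years, values, alpha = 0.05) {
  stopifnot(length(years) == length(values))
  ok <- is.finite(years) & is.finite(values)
  years <- years[ok]; values <- values[ok]
  n <- length(values)
  if (n < 3 || dplyr::n_distinct(years) < 3) {
    stop("trend fit needs at least 3 points in at least 3 distinct years",
         call. = FALSE)
  }
  n_years <- dplyr::n_distinct(years)

  tss <- sum((values - mean(values))^2)
  if (tss == 0) {
    # Constant response: no trend by definition, reported non-significant.
    return(trend_row(0, 0, 0, 1, 0, n, n_years, "none", "ols",
                     exact_fit = FALSE, constant = TRUE))
  }
  fit <- stats::lm(values ~ I(years - mean(years)))
  slope <- unname(stats::coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  r2 <- 1 - rss / tss
  if (rss <= 1e-12 * tss) {
    # Zero residual variance: an exact fit; significant with p = 0, flagged.
    return(trend_row(slope, 0, Inf, 0, 1, n, n_years,
                     if (slope > 0) "increasing" else "decreasing",
                     "ols", exact_fit = TRUE, constant = FALSE))
  }
  sm <- summary(fit)$coefficients
  se <- sm[2, 2]; tval <- sm[2, 3]; p <- sm[2, 4]
  trend_row(slope, se, tval, p, r2, n, n_years,
            trend_direction(slope, p, alpha), "ols",
            exact_fit = FALSE, constant = FALSE)
}

trend_direction <- function(slope, p, alpha) {
  if (is.na(p) || p > alpha || slope == 0) "none"
  else if (slope > 0) "increasing" else "decreasing"
}

trend_row <- function(slope, se, t, p, r2, n_points, n_years, direction,
                      method, exact_fit, constant, rho = NA_real_,
                      applicable = TRUE, converged = TRUE) {
  tibble::tibble(slope = slope, se = se, t = t, p = p, r2 = r2,
                 n_points = n_points, n_years = n_years, direction = direction,
                 method = method, exact_fit = exact_fit, constant = constant,
                 rho = rho, applicable = applicable, converged = converged)
}

#' AR(1) generalized least-squares trend
#'
#' Fits the same linear trend under a year-level AR(1) error structure:
#' sites are nested within year, so all observations from year t share a
#' latent year effect whose correlation with year s decays as
#' `rho^|t - s|`, on top of independent observation noise. The covariance
#' `Sigma = sigma_y^2 * rho^|t_i - t_j| + sigma_e^2 * I` is estimated by
#' restricted maximum likelihood (rho searched over [0, 0.95]; REML is used
#' because unrestricted ML shrinks rho badly in series this short once the
#' intercept and trend are estimated) and the slope is tested
#' against a t distribution with `n - 2` degrees of freedom. Because the
#' AR(1) structure needs unique year values, the model applies only to
#' locations whose site set is the same in every year; uneven sampling
#' returns an inapplicable result, and non-convergence falls back to OLS
#' with `converged = FALSE`.
#'
#' @param years Calendar years of the replicate points.
#' @param values Standardized values.
#' @param sites Site identifier per point.
#' @param alpha Significance level.
#' @param rho_max Upper bound of the rho search (default 0.95).
#' @return One-row tibble as [fit_linear_trend()], with `method = "ar1"`,
#'   the ML estimate `rho`, and an `applicable` flag.
#' @export
fit_ar1_trend <- function(years, values, sites, alpha = 0.05, rho_max = 0.95) {
  stopifnot(length(years) == length(values), length(sites) == length(values))
  site_sets <- tapply(sites, years, function(s) paste(sort(unique(s)), collapse = ";"))
  counts <- tapply(sites, years, length)
  if (dplyr::n_distinct(site_sets) > 1 || dplyr::n_distinct(counts) > 1) {
    return(trend_row(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                     length(values), dplyr::n_distinct(years), "none", "ar1",
                     exact_fit = FALSE, constant = FALSE, applicable = FALSE))
  }
  n_years <- dplyr::n_distinct(years)
  if (n_years < 4) {
    stop("AR-1 trend fit needs at least 4 yearly time points", call. = FALSE)
  }
  n <- length(values)
  if (sum((values - mean(values))^2) == 0) {
    return(trend_row(0, 0, 0, 1, 0, n, n_years, "none", "ar1",
                     exact_fit = FALSE, constant = TRUE, rho = 0))
  }

  X <- cbind(1, years - mean(years))
  dmat <- abs(outer(years, years, "-"))
  same <- diag(n)

  # Negative restricted log-likelihood in theta = (rho, log sy, log se),
  # with beta profiled out by GLS at each theta.
  nll <- function(theta) {
    rho <- theta[1]
    Sigma <- exp(2 * theta[2]) * rho^dmat + exp(2 * theta[3]) * same
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Xw <- backsolve(ch, X, transpose = TRUE)
    beta <- gls_beta(ch, X, values)
    r <- values - X %*% beta
    w <- backsolve(ch, r, transpose = TRUE)
    sum(log(diag(ch))) + 0.5 * sum(w^2) +
      0.5 * determinant(crossprod(Xw), logarithm = TRUE)$modulus
  }
  s0 <- stats::sd(values)
  opt <- tryCatch(
    stats::optim(c(0.3, log(s0 / 2), log(s0 / 2)), nll, method = "L-BFGS-B",
                 lower = c(0, log(s0) - 8, log(s0) - 8),
                 upper = c(rho_max, log(s0) + 3, log(s0) + 3)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$convergence != 0) {
    out <- fit_linear_trend(years, values, alpha)
    out$method <- "ar1"
    out$converged <- FALSE
    return(out)
  }
  rho <- opt$par[1]
  Sigma <- exp(2 * opt$par[2]) * rho^dmat + exp(2 * opt$par[3]) * same
  ch <- chol(Sigma)
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, values, transpose = TRUE)
  XtXi <- solve(crossprod(Xw))
  beta <- XtXi %*% crossprod(Xw, yw)
  slope <- beta[2]
  se <- sqrt(XtXi[2, 2])
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  fitted <- X %*% beta
  r2 <- 1 - sum((values - fitted)^2) / sum((values - mean(values))^2)
  trend_row(slope, se, tval, p, max(r2, 0), n, n_years,
            trend_direction(slope, p, alpha), "ar1",
            exact_fit = FALSE, constant = FALSE, rho = rho)
}

gls_beta <- function(ch, X, y) {
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, y, transpose = TRUE)
  qr.coef(qr(Xw), yw)
}

#' Fit trends for every location x trophic-group series
#'
#' Applies [fit_linear_trend()] (and optionally [fit_ar1_trend()]) to the
#' standardized site-year replicate points of every series. Series flagged
#' constant during standardization are reported with a zero, non-significant
#' trend.
#'
#' @param agg Output of [build_location_series()].
#' @param alpha Significance level.
#' @param method `"ols"`, `"ar1"`, or `"both"`.
#' @return Tibble with one row per series x method.
#' @export
fit_trends <- function(agg, alpha = 0.05, method = c("ols", "both", "ar1")) {
  method <- match.arg(method)
  do_ols <- method %in% c("ols", "both")
  do_ar1 <- method %in% c("ar1", "both")
  agg$site_repl |>
    dplyr::group_by(.data$region, .data$location_id, .data$trophic_group) |>
    dplyr::group_modify(function(d, key) {
      out <- list()
      if (any(d$constant)) {
        r <- trend_row(0, 0, 0, 1, 0, nrow(d), dplyr::n_distinct(d$year),
                       "none", "ols", exact_fit = FALSE, constant = TRUE)
        if (do_ols) out <- c(out, list(r))
        if (do_ar1) { r$method <- "ar1"; out <- c(out, list(r)) }
      } else {
        if (do_ols) out <- c(out, list(fit_linear_trend(d$year, d$std_value, alpha)))
        if (do_ar1) out <- c(out, list(fit_ar1_trend(d$year, d$std_value,
                                                     d$site_id, alpha)))
      }
      dplyr::bind_rows(out)
    }) |>
    dplyr::ungroup()
}

#' Pearson correlation between two annual series on their common years
#'
#' @param years_a,values_a First series (years and standardized annual means).
#' @param years_b,values_b Second series.
#' @return One-row tibble: `r`, `n_years` (paired years), `undefined` flag set
#'   when either series is constant on the overlap.
#' @export
pair_correlation <- function(years_a, values_a, years_b, values_b) {
  common <- intersect(years_a, years_b)
  if (length(common) < 3) {
    stop("fewer than 3 common years between the two series", call. = FALSE)
  }
  a <- values_a[match(common, years_a)]
  b <- values_b[match(common, years_b)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(tibble::tibble(r = NA_real_, n_years = length(common), undefined = TRUE))
  }
  tibble::tibble(r = stats::cor(a, b), n_years = length(common), undefined = FALSE)
}

#' Fisher transformation with inverse-variance weights
#'
#' Pearson coefficients are bounded and sample-size sensitive; following
#' standard meta-analytic practice they are mapped to Fisher's z = atanh(r),
#' approximately normal with variance 1/(n - 3), and weighted by the inverse
#' of that variance in cross-location regressions. Series pairs with only
#' 3 common years get weight 0 (variance undefined) and coefficients with
#' |r| = 1 get an infinite-z flag; both are excluded from weighted models.
#'
#' @param pc Tibble with columns `r` and `n_years` (e.g. from
#'   [pair_correlations()]).
#' @return The input with `z`, `z_var`, `weight` and `infinite_z` filled in.
#' @export
fisher_transform <- function(pc) {
  r <- pc$r
  infinite <- !is.na(r) & abs(r) >= 1
  z <- ifelse(is.na(r) | infinite, NA_real_, atanh(r))
  pc$z <- z
  pc$z_var <- ifelse(pc$n_years > 3, 1 / (pc$n_years - 3), NA_real_)
  pc$weight <- pmax(pc$n_years - 3, 0)
  pc$weight[is.na(z)] <- 0
  pc$infinite_z <- infinite
  pc
}

#' Adjacent-pair correlations for every location
#'
#' Computes the predator-herbivore and herbivore-algae Pearson coefficients
#' from the standardized annual series of each location, and attaches the
#' Fisher z values and weights. The sign of each coefficient is the trophic
#' forcing diagnostic: positive suggests bottom-up, negative top-down.
#'
#' @param series Annual series tibble from [build_location_series()].
#' @return Tibble: `location_id`, `pair`, `r`, `n_years`, `z`, `z_var`,
#'   `weight`, plus `undefined`/`infinite_z` flags.
#' @export
pair_correlations <- function(series) {
  pairs <- list(predator_herbivore = c("predators", "herbivores"),
                herbivore_algae = c("herbivores", "algae"))
  out <- series |>
    dplyr::group_by(.data$region, .data$location_id) |>
    dplyr::group_modify(function(d, key) {
      purrr::map_dfr(names(pairs), function(pn) {
        ga <- dplyr::filter(d, .data$trophic_group == pairs[[pn]][1],
                            !is.na(.data$std_mean))
        gb <- dplyr::filter(d, .data$trophic_group == pairs[[pn]][2],
                            !is.na(.data$std_mean))
        if (length(intersect(ga$year, gb$year)) < 3) {
          return(tibble::tibble(pair = pn, r = NA_real_,
                                n_years = length(intersect(ga$year, gb$year)),
                                undefined = TRUE))
        }
        dplyr::bind_cols(tibble::tibble(pair = pn),
                         pair_correlation(ga$year, ga$std_mean,
                                          gb$year, gb$std_mean))
      })
    }) |>
    dplyr::ungroup()
  fisher_transform(out)
}
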