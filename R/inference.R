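#' Inverse-variance weighted linear regression
#'
#' Weighted least squares minimizing `sum(w_i * (y_i - x_i' beta)^2)`.
#' Points with zero, missing, or negative weight are excluded before fitting
#' and counted in `n_excluded` (a Fisher-z response from a 3-year series has
#' undefined variance and hence weight 0). With all weights equal the fit
#' reduces to ordinary least squares.
#'
#' @param formula Model formula.
#' @param data Data frame holding response and covariates.
#' @param weights Numeric vector of weights (recycled `1` for OLS).
#' @return A `wls_fit`: list with the underlying `lm` fit, the coefficient
#'   table, `r_squared`, `f_stat`, `df`, `p_value`, the data used, and
#'   exclusion counts.
#' @export
weighted_regression <- function(formula, data, weights = NULL) {
  data <- as.data.frame(data)
  if (is.null(weights)) weights <- rep(1, nrow(data))
  stopifnot(length(weights) == nrow(data))
  keep <- !is.na(weights) & weights > 0
  mf_ok <- stats::complete.cases(stats::model.frame(formula, data, na.action = stats::na.pass))
  keep <- keep & mf_ok
  used <- data[keep, , drop = FALSE]
  w_used <- weights[keep]
  if (nrow(used) < 2) stop("fewer than 2 points with positive weight", call. = FALSE)

  # Embed data and weights in the call (not as a data column, which a `~ .`
  # formula would absorb) so drop1()/update() can re-evaluate it later.
  fit <- eval(call("lm", formula = formula, data = used, weights = w_used))
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    dropped <- colnames(stats::model.matrix(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  fstat <- if (is.null(sm$fstatistic)) NULL else sm$fstatistic
  structure(list(
    fit = fit,
    formula = formula,
    coefficients = coef_table(sm$coefficients),
    r_squared = sm$r.squared,
    f_stat = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    df = if (is.null(fstat)) c(NA, stats::df.residual(fit)) else unname(fstat[2:3]),
    p_value = if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    data = used,
    weights = w_used,
    n_used = nrow(used),
    n_excluded = sum(!keep)
  ), class = "wls_fit")
}

coef_table <- function(cm) {
  tibble::tibble(term = rownames(cm), estimate = cm[, 1], se = cm[, 2],
                 statistic = cm[, 3], p = cm[, 4])
}

#' Fitted curve with pointwise intervals from a weighted fit
#'
#' Intervals use the normal approximation on the model (link) scale; when the
#' response is a Fisher z, `backtransform = TRUE` maps fit and interval
#' through `tanh`, which always lands in [-1, 1], for presentation as
#' correlation coefficients.
#'
#' @param object A `wls_fit`.
#' @param newdata Covariate values to predict at.
#' @param level Interval coverage (default 0.95).
#' @param backtransform Map through `tanh` (for Fisher-z responses).
#' @return Tibble with `fit`, `se`, `lwr`, `upr` alongside `newdata`.
#' @export
predict_wls <- function(object, newdata, level = 0.95, backtransform = FALSE) {
  pr <- stats::predict(object$fit, newdata = newdata, se.fit = TRUE)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  out <- tibble::as_tibble(newdata)
  out$fit <- pr$fit
  out$se <- pr$se.fit
  out$lwr <- pr$fit - zc * pr$se.fit
  out$upr <- pr$fit + zc * pr$se.fit
  if (backtransform) {
    out$fit <- tanh(out$fit); out$lwr <- tanh(out$lwr); out$upr <- tanh(out$upr)
  }
  out
}

#' @export
print.wls_fit <- function(x, ...) {
  cat("Weighted linear regression: ", deparse(x$formula), "\n",
      "n = ", x$n_used, " (", x$n_excluded, " excluded), R^2 = ",
      signif(x$r_squared, 4), ", F(", x$df[1], ", ", x$df[2], ") = ",
      signif(x$f_stat, 4), ", p = ", signif(x$p_value, 4), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Binomial logit model for alternating-trend occurrence
#'
#' Among predator-significant locations (the prerequisite subset), models the
#' probability that the full alternating pattern occurred as a function of
#' latitude and exploitation status. Exploitation is coded with treatment
#' contrasts against the `always_fished` reference. Complete separation is
#' detected from degenerate fitted probabilities and flagged (coefficients
#' are still reported, with a warning); categories with fewer than 5
#' locations trigger a small-sample warning.
#'
#' @param classifications Output of [classify_all()].
#' @param meta Location metadata (latitude, exploitation status).
#' @param formula Model formula (default
#'   `alternating ~ latitude + exploitation_status`).
#' @return A `glm_fit`: list with the `glm` object, coefficient table, `aic`,
#'   `converged`, `separation_flag`, and the model data.
#' @export
logistic_cascade_model <- function(classifications, meta,
                                   formula = alternating ~ latitude + exploitation_status) {
  df <- classifications |>
    dplyr::filter(.data$predator_significant) |>
    dplyr::left_join(dplyr::select(meta, dplyr::all_of(c(
      "location_id", "latitude", "exploitation_status"))), by = "location_id")
  fit_binomial_logit(formula, df)
}

#' Fit a binomial logit model with separation diagnostics
#'
#' @param formula Model formula with a logical/0-1 response.
#' @param data Model data; `exploitation_status`, if present, is releveled to
#'   the `always_fished` reference.
#' @return A `glm_fit` list.
#' @export
fit_binomial_logit <- function(formula, data) {
  data <- as.data.frame(data)
  if ("exploitation_status" %in% names(data)) {
    present <- intersect(EXPLOITATION_STATUSES, unique(data$exploitation_status))
    data$exploitation_status <- factor(data$exploitation_status, levels = present)
    small <- table(data$exploitation_status)
    if (any(small < 5)) {
      warning("exploitation categories with fewer than 5 locations: ",
              paste(names(small)[small < 5], collapse = ", "), call. = FALSE)
    }
  }
  y <- stats::model.response(stats::model.frame(formula, data))
  if (length(unique(y)) < 2) {
    stop("degenerate response: all successes or all failures", call. = FALSE)
  }
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    eval(call("glm", formula = formula,
              family = quote(stats::binomial(link = "logit")), data = data)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned_sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  eps <- 1e-8
  separation <- warned_sep || any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  if (separation) {
    warning("possible complete separation; coefficients unreliable", call. = FALSE)
  }
  structure(list(
    fit = fit,
    formula = formula,
    coefficients = coef_table(summary(fit)$coefficients),
    aic = stats::AIC(fit),
    converged = fit$converged,
    separation_flag = separation,
    data = data
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("Binomial logit model: ", deparse(x$formula), "\n",
      "AIC = ", signif(x$aic, 6),
      if (x$separation_flag) "  [separation flagged]" else "", "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Backward stepwise term removal by AIC among non-significant terms
#'
#' From the full model, repeatedly considers the terms whose significance
#' exceeds `alpha` (multi-level factors tested as a block: likelihood-ratio
#' test for GLMs, F test for linear models) and removes the one whose removal
#' lowers AIC the most; stops when every remaining term is significant or no
#' removal lowers AIC. An intercept-only model is a valid endpoint.
#'
#' @param object A `wls_fit` or `glm_fit`.
#' @param alpha Retention threshold on the block p-value (default 0.05).
#' @return List with `final` (refitted object of the same class) and `trace`
#'   (tibble: step, model terms, AIC, dropped term and its p-value).
#' @export
backward_stepwise <- function(object, alpha = 0.05) {
  stopifnot(inherits(object, c("wls_fit", "glm_fit")))
  is_glm <- inherits(object, "glm_fit")
  inner <- object$fit
  data <- object$data
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    d1 <- stats::drop1(inner, test = if (is_glm) "LRT" else "F")
    terms_now <- attr(stats::terms(inner), "term.labels")
    cur_aic <- d1["<none>", "AIC"]
    if (length(terms_now) == 0) {
      trace[[step]] <- tibble::tibble(step = step,
                                      terms = "(intercept only)",
                                      aic = cur_aic, dropped = NA_character_,
                                      drop_p = NA_real_)
      break
    }
    tab <- d1[terms_now, , drop = FALSE]
    pcol <- grep("^Pr\\(", names(tab), value = TRUE)[1]
    pvals <- tab[[pcol]]
    cand <- which(pvals > alpha & tab$AIC < cur_aic)
    if (length(cand) == 0) {
      trace[[step]] <- tibble::tibble(step = step,
                                      terms = paste(terms_now, collapse = " + "),
                                      aic = cur_aic, dropped = NA_character_,
                                      drop_p = NA_real_)
      break
    }
    drop_i <- cand[which.min(tab$AIC[cand])]
    dropped <- terms_now[drop_i]
    trace[[step]] <- tibble::tibble(step = step,
                                    terms = paste(terms_now, collapse = " + "),
                                    aic = cur_aic, dropped = dropped,
                                    drop_p = pvals[drop_i])
    new_formula <- stats::update(stats::formula(inner),
                                 stats::as.formula(paste(". ~ . -", dropped)))
    inner <- if (is_glm) {
      eval(call("glm", formula = new_formula,
                family = quote(stats::binomial(link = "logit")), data = data))
    } else {
      eval(call("lm", formula = new_formula, data = data,
                weights = object$weights))
    }
  }
  final <- if (is_glm) {
    fit_binomial_logit(stats::formula(inner), data)
  } else {
    weighted_regression(stats::formula(inner), data, object$weights)
  }
  list(final = final, trace = dplyr::bind_rows(trace))
}

#' Weighted Fisher-z regression of an adjacent-pair correlation on latitude
#'
#' Regresses the Fisher z of the chosen trophic-group pair on signed latitude
#' with inverse-variance weights `n_years - 3`. Pairs with only 3 common
#' years carry weight 0 and are excluded by default; setting
#' `min_years_weighted = 3` assigns them unit weight instead so every
#' location enters the fit.
#'
#' @param pairs Output of [pair_correlations()].
#' @param meta Location metadata with `latitude`.
#' @param pair `"herbivore_algae"` or `"predator_herbivore"`.
#' @param min_years_weighted Minimum paired years for inverse-variance
#'   weighting (default 4).
#' @return A `wls_fit`.
#' @export
fisherz_latitude_model <- function(pairs, meta, pair = "herbivore_algae",
                                   min_years_weighted = 4) {
  df <- pairs |>
    dplyr::filter(.data$pair == !!pair, !is.na(.data$z)) |>
    dplyr::left_join(dplyr::select(meta, dplyr::all_of(c("location_id", "latitude"))),
                     by = "location_id")
  w <- df$weight
  if (min_years_weighted <= 3) w[df$n_years == 3] <- 1
  weighted_regression(z ~ latitude, df, w)
}

#' Per-group trend models against latitude and exploitation status
#'
#' For each trophic group, regresses the standardized trend slope on signed
#' latitude (continuous) and, separately, on exploitation status
#' (categorical), weighting by the inverse squared standard error of each
#' slope; both models go through backward stepwise selection. Also emits the
#' weighted mean trend with a 95% confidence interval per exploitation
#' category for reporting. A group observed under a single exploitation
#' category skips the categorical model with a warning.
#'
#' @param trends Trend table from [fit_trends()].
#' @param meta Location metadata.
#' @param method Trend method to use (default `"ols"`).
#' @param alpha Stepwise retention threshold.
#' @return Named list (per trophic group) of `latitude` / `exploitation`
#'   stepwise results and `category_means`.
#' @export
trend_vs_covariate_models <- function(trends, meta, method = "ols", alpha = 0.05) {
  df <- trends |>
    dplyr::filter(.data$method == !!method, !.data$constant, .data$applicable) |>
    dplyr::left_join(dplyr::select(meta, dplyr::all_of(c(
      "location_id", "latitude", "exploitation_status"))), by = "location_id") |>
    dplyr::mutate(w = ifelse(is.na(.data$se) | .data$se <= 0, 0, 1 / .data$se^2))

  out <- lapply(split(df, df$trophic_group), function(g) {
    lat <- backward_stepwise(weighted_regression(slope ~ latitude, g, g$w), alpha)
    expl <- NULL
    cats <- unique(g$exploitation_status[g$w > 0])
    if (length(cats) >= 2) {
      g2 <- g
      g2$exploitation_status <- factor(g2$exploitation_status,
                                       levels = intersect(EXPLOITATION_STATUSES, cats))
      expl <- backward_stepwise(
        weighted_regression(slope ~ exploitation_status, g2, g2$w), alpha)
    } else {
      warning("single exploitation category for group; categorical model skipped",
              call. = FALSE)
    }
    means <- g |>
      dplyr::filter(.data$w > 0) |>
      dplyr::group_by(.data$exploitation_status) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_slope = sum(.data$w * .data$slope) / sum(.data$w),
        se = sqrt(1 / sum(.data$w)),
        .groups = "drop"
      ) |>
      dplyr::mutate(lwr = .data$mean_slope - 1.96 * .data$se,
                    upr = .data$mean_slope + 1.96 * .data$se)
    list(latitude = lat, exploitation = expl, category_means = means)
  })
  out[intersect(TROPHIC_GROUPS, names(out))]
}
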