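#' Run the full analysis chain
#'
#' Simulates (or takes) a survey dataset, validates it, aggregates to
#' standardized annual series, fits per-series trends, computes adjacent-pair
#' correlations with Fisher-z weights, applies the alternating-trend cascade
#' classification, and fits the cross-location models (Fisher-z latitude
#' regressions, per-group trend models, and the binomial cascade model with
#' stepwise selection). Deterministic given the configuration seed.
#'
#' @param config A [sim_config()] (e.g. [default_sim_config()]) used to
#'   simulate inputs, or `NULL` when `records`/`meta` are supplied.
#' @param records,meta Survey records and location metadata, if not simulated.
#' @param alpha Significance level used throughout (must be in (0, 1)).
#' @param method Trend method: `"ols"`, `"ar1"`, or `"both"`; classification
#'   and inference use the OLS calls unless `method = "ar1"`.
#' @return A `reeftrends_run`: list with every stage's tables (`validation`,
#'   `series`, `trends`, `pairs`, `classifications`, `prevalence`, model
#'   fits) plus a `summary` list of headline numbers.
#' @export
run_pipeline <- function(config = NULL, records = NULL, meta = NULL,
                         alpha = 0.05, method = c("both", "ols", "ar1")) {
  method <- match.arg(method)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  }
  truth <- NULL
  if (is.null(records)) {
    stopifnot(inherits(config, "sim_config"))
    sim <- simulate_dataset(config)
    records <- sim$records
    meta <- sim$meta
    truth <- sim$truth
  }
  meta <- validate_location_meta(meta)
  validation <- validate_dataset(records, meta)
  agg <- build_location_series(records, meta)
  trends <- fit_trends(agg, alpha = alpha, method = method)
  pairs <- pair_correlations(agg$series)
  class_method <- if (method == "ar1") "ar1" else "ols"
  classifications <- classify_all(trends, method = class_method)
  prevalence <- summarize_prevalence(classifications)
  prevalence_region <- summarize_prevalence(classifications, grouping = "region")

  pred <- trends |>
    dplyr::filter(.data$method == class_method,
                  .data$trophic_group == "predators")
  n_sig <- sum(pred$direction != "none")
  excess <- excess_over_chance(n_sig, nrow(pred), alpha)

  ha_model <- backward_stepwise(fisherz_latitude_model(pairs, meta, "herbivore_algae"))
  ph_model <- backward_stepwise(fisherz_latitude_model(pairs, meta, "predator_herbivore"))
  cascade_model <- NULL
  sub <- dplyr::filter(classifications, .data$predator_significant)
  if (nrow(sub) > 0 && length(unique(sub$alternating)) == 2) {
    cascade_model <- withCallingHandlers(
      backward_stepwise(logistic_cascade_model(classifications, meta), alpha),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  trend_models <- withCallingHandlers(
    trend_vs_covariate_models(trends, meta, method = class_method, alpha = alpha),
    warning = function(w) invokeRestart("muffleWarning"))

  summary <- list(
    n_locations = dplyr::n_distinct(meta$location_id),
    n_series = dplyr::n_distinct(paste(records$location_id, records$trophic_group)),
    alpha = alpha,
    n_predator_significant = n_sig,
    n_predator_increasing = sum(pred$direction == "increasing"),
    n_predator_decreasing = sum(pred$direction == "decreasing"),
    n_alternating = prevalence$n_alternating,
    n_partial_alternating = prevalence$n_partial_alternating,
    pct_alternating = prevalence$pct_alternating,
    excess_over_chance = excess$ratio,
    retained_terms = list(
      herbivore_algae_z = final_terms(ha_model),
      predator_herbivore_z = final_terms(ph_model),
      cascade_glm = if (is.null(cascade_model)) character(0)
                    else final_terms(cascade_model))
  )
  structure(list(validation = validation, series = agg$series,
                 site_repl = agg$site_repl, trends = trends, pairs = pairs,
                 classifications = classifications, prevalence = prevalence,
                 prevalence_region = prevalence_region,
                 ha_model = ha_model, ph_model = ph_model,
                 cascade_model = cascade_model, trend_models = trend_models,
                 meta = meta, truth = truth, summary = summary),
            class = "reeftrends_run")
}

final_terms <- function(stepped) {
  attr(stats::terms(stepped$final$fit), "term.labels")
}

#' @export
print.reeftrends_run <- function(x, ...) {
  s <- x$summary
  cat("reeftrends pipeline run\n",
      "  locations: ", s$n_locations, " (", s$n_series, " trophic-group series)\n",
      "  significant predator trends (alpha = ", s$alpha, "): ",
      s$n_predator_significant, " (", s$n_predator_increasing, " up, ",
      s$n_predator_decreasing, " down)  ~",
      round(s$excess_over_chance, 1), "x chance\n",
      "  alternating-trend locations: ", s$n_alternating, " of ",
      s$n_predator_significant, " predator-significant (",
      ifelse(is.na(s$pct_alternating), "NA", round(s$pct_alternating)), "%), ",
      s$n_partial_alternating, " partial\n",
      "  retained terms: herbivore-algae z ~ ",
      fmt_terms(s$retained_terms$herbivore_algae_z),
      "; cascade GLM ~ ", fmt_terms(s$retained_terms$cascade_glm), "\n",
      sep = "")
  invisible(x)
}

fmt_terms <- function(tt) if (length(tt) == 0) "1" else paste(tt, collapse = " + ")
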