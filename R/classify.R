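#' Alternating-trend cascade classification for one location
#'
#' A location qualifies as showing a community-level trophic cascade signal
#' when all three trophic groups change significantly over time with adjacent
#' groups trending in opposite directions (predators up, herbivores down,
#' algae up — or the mirror pattern). A significant predator trend is the
#' prerequisite: only with a real change at the top would lower groups be
#' expected to respond under top-down control. Locations where predators and
#' herbivores show significant opposing trends but algae does not respond are
#' tallied separately under `partial_alternating`.
#'
#' @param trends Trend results for one location: one row per trophic group
#'   (a single method).
#' @return One-row tibble: per-group directions, `predator_significant`,
#'   `alternating`, `partial_alternating`, and a `pattern` string such as
#'   `"P+H-A+"`.
#' @export
classify_location <- function(trends) {
  if (!setequal(trends$trophic_group, TROPHIC_GROUPS) ||
      nrow(trends) != 3) {
    stop("classification needs exactly one trend result per trophic group",
         call. = FALSE)
  }
  dir <- trends$direction[match(TROPHIC_GROUPS, trends$trophic_group)]
  sgn <- c(increasing = 1, decreasing = -1, none = 0)[dir]
  pred_sig <- dir[1] != "none"
  all_sig <- all(dir != "none")
  alternating <- pred_sig && all_sig && sgn[1] == -sgn[2] && sgn[2] == -sgn[3]
  partial <- pred_sig && dir[2] != "none" && sgn[1] == -sgn[2] && !alternating
  tibble::tibble(
    predator_direction = dir[1], herbivore_direction = dir[2],
    algae_direction = dir[3],
    predator_significant = pred_sig,
    alternating = alternating,
    partial_alternating = partial,
    pattern = paste0("P", dir_symbol(dir[1]), "H", dir_symbol(dir[2]),
                     "A", dir_symbol(dir[3]))
  )
}

dir_symbol <- function(d) c(increasing = "+", decreasing = "-", none = "0")[d]

#' Classify every location in a trend table
#'
#' @param trends Trend table from [fit_trends()].
#' @param method Which method's trend calls to classify (default `"ols"`).
#' @return Tibble with one classification row per location.
#' @export
classify_all <- function(trends, method = "ols") {
  trends |>
    dplyr::filter(.data$method == !!method) |>
    dplyr::group_by(.data$region, .data$location_id) |>
    dplyr::group_modify(function(d, key) classify_location(d)) |>
    dplyr::ungroup()
}

#' Prevalence of alternating trends among predator-significant locations
#'
#' Summarizes, overall or within a grouping (region or exploitation status),
#' how many locations met the predator-trend prerequisite and what fraction
#' of those showed the full alternating pattern. The percentage is reported
#' both exactly and rounded to the nearest integer for display; a group with
#' no predator-significant locations has an undefined (NA) percentage rather
#' than zero.
#'
#' @param classifications Output of [classify_all()].
#' @param meta Location metadata (needed for `exploitation_status` grouping).
#' @param grouping `"all"`, `"region"`, or `"exploitation_status"`.
#' @return Tibble with counts and percentages per group.
#' @export
summarize_prevalence <- function(classifications, meta = NULL,
                                 grouping = c("all", "region", "exploitation_status")) {
  grouping <- match.arg(grouping)
  stopifnot(nrow(classifications) > 0)
  df <- classifications
  if (grouping == "exploitation_status") {
    if (is.null(meta)) stop("meta required for exploitation_status grouping",
                            call. = FALSE)
    df <- dplyr::left_join(df,
                           dplyr::select(meta, dplyr::all_of(c("location_id", "exploitation_status"))),
                           by = "location_id")
  }
  keys <- switch(grouping, all = character(0), region = "region",
                 exploitation_status = "exploitation_status")
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_locations = dplyr::n(),
      n_predator_significant = sum(.data$predator_significant),
      n_alternating = sum(.data$alternating),
      n_partial_alternating = sum(.data$partial_alternating),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_alternating = ifelse(.data$n_predator_significant == 0, NA_real_,
                               100 * .data$n_alternating / .data$n_predator_significant),
      pct_alternating_display = round(.data$pct_alternating)
    )
}

#' Observed significant trends relative to the chance expectation
#'
#' At significance level `alpha`, `n_tests * alpha` significant trends are
#' expected under the global null; the ratio of the observed count to that
#' expectation expresses how far the data exceed chance ("about five times
#' more than expected").
#'
#' @param n_significant Observed significant trends.
#' @param n_tests Number of tests performed.
#' @param alpha Per-test significance level.
#' @return List with `ratio` (exact) and `display` (nearest integer).
#' @export
excess_over_chance <- function(n_significant, n_tests, alpha = 0.05) {
  stopifnot(n_tests > 0, alpha > 0, alpha < 1)
  ratio <- n_significant / (n_tests * alpha)
  list(ratio = ratio, display = round(ratio))
}
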