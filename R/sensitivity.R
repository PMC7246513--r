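#' Scenario configuration for the sensitivity analysis
#'
#' One cell of the scenario grid: the fire-day percentile threshold, the
#' months defining winter (wood-heater season), and whether polluted
#' transition-month days with a predicted source are included in the burden
#' and cost computation.
#'
#' @param percentile Fire-day percentile, in (50, 100).
#' @param winter_months Months defining winter.
#' @param summer_months Months defining summer.
#' @param include_predicted Keep predicted transition-month days?
#' @param label Scenario label (auto-built when NULL).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(percentile = 95, winter_months = 5:8,
                            summer_months = c(11, 12, 1, 2),
                            include_predicted = TRUE, label = NULL) {
  if (percentile <= 50 || percentile >= 100) {
    stop("percentile must lie in (50, 100)", call. = FALSE)
  }
  scheme <- season_scheme(winter_months, summer_months)
  label <- label %||% sprintf(
    "p%g_winter%s_%s", percentile,
    paste(range(winter_months), collapse = "-"),
    if (include_predicted) "all_months" else "no_predicted")
  structure(list(percentile = percentile, scheme = scheme,
                 include_predicted = include_predicted, label = label),
            class = "scenario_config")
}

#' Run the full burden-and-cost pipeline under one scenario
#'
#' Reclassifies the area-day exposure table under the scenario's seasonal
#' scheme and percentile (retraining the transition classifier, same seed
#' across scenarios for comparability), recomputes health impacts and
#' costs, and returns the per-source indicator row set. When
#' `include_predicted` is FALSE, polluted transition-month days are dropped
#' before the burden, cost and day-count computations.
#'
#' @param area_days Output of [build_area_days()].
#' @param areas,rates,drf,model Pipeline inputs (see
#'   [compute_health_impacts()] and [cost_model()]).
#' @param scenario A [scenario_config()].
#' @param seed Classifier seed.
#' @return Tibble of per-source indicators with the scenario `label` and
#'   `months_included`.
#' @export
run_scenario <- function(area_days, areas, rates = default_baseline_rates(),
                         drf = default_dose_response(),
                         model = cost_model(), scenario = scenario_config(),
                         seed = 1) {
  stopifnot(inherits(scenario, "scenario_config"))
  classified <- tryCatch(
    classify_days(area_days, scheme = scenario$scheme,
                  percentile = scenario$percentile, seed = seed),
    error = function(e) stop("scenario '", scenario$label, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!scenario$include_predicted) {
    # predicted transition days stay in the calendar (annual-mean
    # denominators) but contribute no source, burden or cost
    pred <- classified$label_origin == "predicted"
    classified$day_type[pred] <- "unpolluted"
    classified$pm25_attributable[pred] <- 0
  }
  impacts <- compute_health_impacts(classified, areas, rates, drf)
  costs <- cost_impacts(impacts$summary, model)
  cost_indicators(costs, classified, model) |>
    mutate(label = scenario$label,
           percentile = scenario$percentile,
           months_included = if (scenario$include_predicted) "all"
                             else "excluding_predicted")
}

#' Run a scenario grid and tabulate indicator ranges
#'
#' Crosses percentiles, winter definitions and predicted-day flags into a
#' scenario set, runs each through [run_scenario()], and summarizes the
#' min/max range of every indicator per source and months-included group
#' alongside the main-scenario value.
#'
#' @inheritParams run_scenario
#' @param percentiles Fire-day percentiles to scan.
#' @param winter_defs List of winter month vectors.
#' @param predicted_flags Logical vector of include-predicted settings.
#' @param main Main-scenario config used for the reference column.
#' @return List with `results` (one row per scenario x source) and
#'   `ranges` (per source x months-included x indicator: main, min, max).
#' @export
scenario_grid <- function(area_days, areas,
                          rates = default_baseline_rates(),
                          drf = default_dose_response(),
                          model = cost_model(),
                          percentiles = c(75, 90, 95, 99),
                          winter_defs = list(5:8, 5:7, 6:7),
                          predicted_flags = c(TRUE, FALSE),
                          main = scenario_config(), seed = 1) {
  stopifnot(length(percentiles) > 0, length(winter_defs) > 0)
  grid <- expand.grid(p = seq_along(percentiles), w = seq_along(winter_defs),
                      f = seq_along(predicted_flags))
  results <- purrr::pmap_dfr(grid, function(p, w, f) {
    run_scenario(area_days, areas, rates, drf, model,
                 scenario_config(percentiles[p], winter_defs[[w]],
                                 include_predicted = predicted_flags[f]),
                 seed = seed)
  })
  main_res <- run_scenario(area_days, areas, rates, drf, model, main,
                           seed = seed)
  long <- results |>
    select("source", "months_included", "label",
           "total_cost", "cost_per_day", "cost_per_year",
           "cost_per_woodstove_year") |>
    tidyr::pivot_longer(c("total_cost", "cost_per_day", "cost_per_year",
                          "cost_per_woodstove_year"),
                        names_to = "indicator", values_to = "value") |>
    filter(!is.na(.data$value))
  ranges <- long |>
    group_by(.data$source, .data$months_included, .data$indicator) |>
    summarise(min = min(.data$value), max = max(.data$value),
              .groups = "drop") |>
    left_join(main_res |>
                select("source", "total_cost", "cost_per_day",
                       "cost_per_year", "cost_per_woodstove_year") |>
                tidyr::pivot_longer(-"source", names_to = "indicator",
                                    values_to = "main"),
              by = c("source", "indicator"))
  list(results = results, ranges = ranges, main = main_res)
}
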