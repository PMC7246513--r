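#' Run the full exposure-to-cost pipeline on a smoke world
#'
#' Convenience orchestrator: valid daily station means, heating degree
#' days, inverse-distance interpolation to area centroids, day-type
#' classification with the percentile fire-day rule and the transition
#' classifier, health-impact assessment, and cost valuation with policy
#' indicators.
#'
#' @param world A [generate_world()] result, or a list with the same
#'   elements read from disk via [read_world_inputs()] (plus `areas`).
#' @param scheme A [season_scheme()].
#' @param percentile Fire-day percentile threshold.
#' @param model A [cost_model()].
#' @param drf Dose-response table.
#' @param rates Baseline rates (defaults to the world's, else packaged
#'   defaults).
#' @param radius_km,power Interpolation settings.
#' @param seed Classifier seed.
#' @return List with `area_days`, `classified`, `day_type_summary`,
#'   `impacts` (list), `costs`, and `indicators`.
#' @export
run_pipeline <- function(world, scheme = season_scheme(), percentile = 95,
                         model = cost_model(), drf = default_dose_response(),
                         rates = NULL, radius_km = 100, power = 2, seed = 1) {
  rates <- rates %||% world$baseline_rates %||% default_baseline_rates()
  daily_pm <- daily_station_means(world$hourly)
  area_days <- build_area_days(daily_pm, world$pm_stations, world$met,
                               world$met_stations, world$areas,
                               radius_km = radius_km, power = power)
  classified <- classify_days(area_days, scheme = scheme,
                              percentile = percentile, seed = seed)
  impacts <- compute_health_impacts(classified, world$areas, rates, drf)
  costs <- cost_impacts(impacts$summary, model)
  n_stoves <- if (!is.null(world$areas$woodstoves)) {
    sum(world$areas$woodstoves)
  } else model$n_woodstoves
  model$n_woodstoves <- n_stoves
  list(
    area_days = area_days,
    classified = classified,
    day_type_summary = summarize_day_types(classified),
    impacts = impacts,
    costs = costs,
    indicators = cost_indicators(costs, classified, model)
  )
}
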