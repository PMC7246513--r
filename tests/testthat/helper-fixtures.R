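# fixtures are generated in code and cached for the session so the slower
# worlds are built once across test files
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 6-area, two-full-year world: two winters, one complete fire season plus
# two half seasons
small_world <- function() {
  cached("small_world", generate_world(generator_config(
    n_areas = 6, n_pm_stations = 6, n_met_stations = 6,
    start_date = "2016-01-01", end_date = "2017-12-31", seed = 11)))
}

small_area_days <- function() {
  cached("small_area_days", {
    w <- small_world()
    build_area_days(daily_station_means(w$hourly), w$pm_stations,
                    w$met, w$met_stations, w$areas)
  })
}

small_classified <- function() {
  cached("small_classified",
         classify_days(small_area_days(), seed = 11))
}

# default-scale world used by the parameter-recovery checks
recovery_world <- function() {
  cached("recovery_world", generate_world(generator_config(seed = 1)))
}

recovery_pipeline <- function() {
  cached("recovery_pipeline",
         suppressWarnings(run_pipeline(recovery_world(), seed = 1)))
}

# hand-built one-area classified table with known WHS days, for closed-form
# burden oracles
toy_classified <- function(n_whs = 40, attr = 5) {
  dates <- seq(as.Date("2017-01-01"), as.Date("2017-12-31"), by = "day")
  month <- as.integer(format(dates, "%m"))
  whs <- which(month %in% 5:8)[seq_len(n_whs)]
  tibble::tibble(
    area_id = "A01", date = dates,
    pm25 = 1.4, hdd = 5, tmin = 5, tmax = 15,
    day_type = ifelse(seq_along(dates) %in% whs, "WHS", "unpolluted"),
    pm25_attributable = ifelse(seq_along(dates) %in% whs, attr, 0),
    label_origin = ifelse(seq_along(dates) %in% whs, "rule_season",
                          "rule_unpolluted")
  )
}

toy_areas <- function() {
  tibble::tibble(area_id = "A01", region_id = "R1", x_km = 0, y_km = 0,
                 population = 10000, pop_0_17 = 2200, pop_18_64 = 6000,
                 pop_65plus = 1800, pop_30plus = 6200, woodstoves = 1300)
}
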