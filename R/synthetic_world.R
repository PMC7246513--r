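#' Default diurnal weight profile for wood-heater smoke
#'
#' Hourly weights (hour 0-23, local time) describing the within-day shape of
#' wood-heater PM2.5: a large overnight peak when heaters are banked down and
#' dispersion is poorest, and a smaller early-morning peak when heaters are
#' relit. Weights are rescaled internally so their mean is 1, making the
#' daily mean of the wood-heater term equal to the configured daily
#' amplitude.
#'
#' @return Numeric vector of 24 non-negative weights.
#' @export
default_diurnal_profile <- function() {
  c(1.8, 1.6, 1.2, 0.9, 0.8, 0.9, 1.3, 1.5, 1.2, 0.8, 0.6, 0.5,
    0.45, 0.45, 0.5, 0.6, 0.7, 0.9, 1.2, 1.5, 1.9, 2.2, 2.3, 2.1)
}

#' Default synthetic baseline incidence rates
#'
#' Annual baseline incidence rates (cases per person-year) by outcome and
#' age band for the synthetic population. Values are plausible for a
#' temperate Australian state: all-cause mortality near 12.5 per 1000 in the
#' 30+ band and 8.5 per 1000 overall, cardiovascular and respiratory
#' admission rates near 2% per year, and asthma emergency-department visit
#' rates highest in children. They are synthetic inputs, not estimates for
#' any real jurisdiction.
#'
#' @return A tibble with columns `outcome`, `age_group`, `rate`
#'   (cases per person-year).
#' @export
default_baseline_rates <- function() {
  tibble::tribble(
    ~outcome,              ~age_group, ~rate,
    "all_cause_mortality", "30plus",   0.0125,
    "all_cause_mortality", "all",      0.0085,
    "cvd_admission",       "all",      0.018,
    "rsp_admission",       "all",      0.020,
    "asthma_ed",           "0_17",     0.0060,
    "asthma_ed",           "18_64",    0.0018,
    "asthma_ed",           "65plus",   0.0025
  )
}

#' Configuration for the synthetic smoke world generator
#'
#' Bundles and validates the knobs of [generate_world()]. Defaults describe
#' a cool-temperate island setting: a low summer background (1.4 ug/m3),
#' winter wood-smoke raising polluted-day means to roughly 8 ug/m3, rare
#' heavy-tailed summer fire events whose maxima can reach hundreds of
#' ug/m3, and a seasonal temperature cycle whose cold half drives heating
#' degree days.
#'
#' @param n_areas Number of statistical areas (exposure units).
#' @param n_pm_stations Number of PM2.5 monitoring stations. Stations are
#'   placed at area centroids (with small jitter) so most areas have a
#'   monitor within a few km, mimicking a dense urban network.
#' @param n_met_stations Number of meteorological stations.
#' @param start_date,end_date Inclusive study period (`Date` or coercible).
#' @param background_mean Non-smoke background PM2.5 (ug/m3); the quantity
#'   the counterfactual estimator should recover.
#' @param whs_winter_amplitude Daily-mean wood-heater PM2.5 (ug/m3) added on
#'   a reference winter day; scaled day-to-day by heating degree days.
#' @param whs_diurnal_profile 24 non-negative hourly weights shaping the
#'   wood-heater term within a day; rescaled to mean 1.
#' @param lfs_event_rate Expected number of fire-smoke events per area per
#'   summer season.
#' @param lfs_event_magnitude Median daily-mean PM2.5 (ug/m3) added by a
#'   fire event; magnitudes are lognormal so the tail is heavy.
#' @param lfs_magnitude_sdlog Lognormal sdlog of event magnitudes.
#' @param temp_annual_mean,temp_annual_amplitude Annual mean and half-range
#'   of daily mean temperature (deg C); coldest mid-July (southern
#'   hemisphere phase).
#' @param temp_daily_range Average tmax - tmin (deg C).
#' @param noise_sd SD of zero-mean Gaussian hourly measurement noise
#'   (ug/m3); kept small relative to the background so the 0.05 ug/m3
#'   positivity floor almost never binds and daily means stay unbiased.
#' @param background_cv Day-to-day coefficient of variation of the
#'   background: each area-day draws its background from a mean-one
#'   lognormal scaled by `background_mean`, so clean-day daily means vary
#'   realistically while averaging to the configured background.
#' @param missing_hour_rate Probability an hourly record is absent.
#' @param population_range Two-element range for area populations.
#' @param domain_km Side of the square planar domain (km).
#' @param seed Integer seed; fixed seed gives bit-identical worlds.
#'
#' @return A validated list of class `smoke_generator_config`.
#' @export
generator_config <- function(n_areas = 20,
                             n_pm_stations = 18,
                             n_met_stations = 18,
                             start_date = "2016-01-01",
                             end_date = "2018-12-31",
                             background_mean = 1.4,
                             whs_winter_amplitude = 6.3,
                             whs_diurnal_profile = default_diurnal_profile(),
                             lfs_event_rate = 1.2,
                             lfs_event_magnitude = 12,
                             lfs_magnitude_sdlog = 1.1,
                             temp_annual_mean = 12,
                             temp_annual_amplitude = 6,
                             temp_daily_range = 8,
                             noise_sd = 0.35,
                             background_cv = 0.28,
                             missing_hour_rate = 0.02,
                             population_range = c(3000, 25000),
                             domain_km = 160,
                             seed = 1) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || end_date < start_date) {
    stop("inconsistent date range: end_date must not precede start_date",
         call. = FALSE)
  }
  if (n_areas < 1 || n_pm_stations < 1 || n_met_stations < 1) {
    stop("need at least one area, one PM station and one met station",
         call. = FALSE)
  }
  mags <- c(background_mean, whs_winter_amplitude, lfs_event_rate,
            lfs_event_magnitude, lfs_magnitude_sdlog, temp_daily_range,
            noise_sd, background_cv, missing_hour_rate, whs_diurnal_profile)
  if (any(!is.finite(mags)) || any(mags < 0)) {
    stop("all generator magnitudes must be finite and >= 0", call. = FALSE)
  }
  if (length(whs_diurnal_profile) != 24) {
    stop("whs_diurnal_profile must have 24 hourly weights", call. = FALSE)
  }
  if (length(population_range) != 2 || population_range[1] > population_range[2]) {
    stop("population_range must be an increasing pair", call. = FALSE)
  }
  structure(list(
    n_areas = as.integer(n_areas),
    n_pm_stations = as.integer(n_pm_stations),
    n_met_stations = as.integer(n_met_stations),
    start_date = start_date, end_date = end_date,
    background_mean = background_mean,
    whs_winter_amplitude = whs_winter_amplitude,
    whs_diurnal_profile = whs_diurnal_profile / mean(whs_diurnal_profile),
    lfs_event_rate = lfs_event_rate,
    lfs_event_magnitude = lfs_event_magnitude,
    lfs_magnitude_sdlog = lfs_magnitude_sdlog,
    temp_annual_mean = temp_annual_mean,
    temp_annual_amplitude = temp_annual_amplitude,
    temp_daily_range = temp_daily_range,
    noise_sd = noise_sd,
    background_cv = background_cv,
    missing_hour_rate = missing_hour_rate,
    population_range = population_range,
    domain_km = domain_km,
    seed = as.integer(seed)
  ), class = "smoke_generator_config")
}

# summer season id: Nov/Dec belong to the season starting that year,
# Jan/Feb to the season that started the previous year
.summer_season <- function(date) {
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  ifelse(m >= 11, y, y - 1)
}

#' Generate a synthetic smoke world with known ground truth
#'
#' Builds a planar monitor network, hourly PM2.5, daily station
#' temperatures, area populations and baseline rates, together with a truth
#' table recording, for every area-day, the injected source label
#' (`unpolluted`, `WHS` or `LFS`) and the true attributable PM2.5 (the
#' injected daily-mean source term, excluding measurement noise).
#'
#' Hourly PM2.5 at a station is `background + WHS term + LFS term + noise`.
#' The wood-heater term is active through winter (May-August) and
#' stochastically on cold transition-month days, scales with heating degree
#' days, and follows a bimodal diurnal profile (large overnight peak,
#' smaller early-morning peak). Fire events are sporadic multi-day episodes
#' in summer (November-February) and, at reduced rate and magnitude, on
#' warm transition-month days (prescribed-burn weather); daily magnitudes
#' are lognormal, so maxima reach hundreds of ug/m3 while most events are
#' modest. A day carries a single source: fire days in transition months
#' suppress the wood-heater term.
#'
#' @param config A [generator_config()].
#' @return A list of class `smoke_world` with elements `areas`,
#'   `pm_stations`, `met_stations`, `hourly`, `met`, `truth`,
#'   `baseline_rates`, `dates` and `config`.
#' @export
generate_world <- function(config = generator_config()) {
  stopifnot(inherits(config, "smoke_generator_config"))
  set.seed(config$seed)
  dates <- seq(config$start_date, config$end_date, by = "day")
  n_days <- length(dates)
  month <- as.integer(format(dates, "%m"))
  yday <- as.integer(format(dates, "%j"))

  ## ---- areas ------------------------------------------------------------
  n_areas <- config$n_areas
  ax <- runif(n_areas, 0, config$domain_km)
  ay <- runif(n_areas, 0, config$domain_km)
  region <- paste0("R", 1 + (ax > config$domain_km / 2) +
                     2 * (ay > config$domain_km / 2))
  pop <- round(runif(n_areas, config$population_range[1],
                     config$population_range[2]))
  p017 <- runif(n_areas, 0.20, 0.24)
  p65 <- runif(n_areas, 0.16, 0.20)
  p30 <- runif(n_areas, 0.60, 0.64)
  areas <- tibble::tibble(
    area_id = sprintf("A%02d", seq_len(n_areas)),
    region_id = region,
    x_km = ax, y_km = ay,
    population = pop,
    pop_0_17 = round(pop * p017),
    pop_18_64 = pop - round(pop * p017) - round(pop * p65),
    pop_65plus = round(pop * p65),
    pop_30plus = round(pop * p30),
    woodstoves = round(0.133 * pop * runif(n_areas, 0.8, 1.2))
  )

  ## ---- stations (placed at area centroids with jitter) -------------------
  place_stations <- function(n, prefix) {
    host <- sample(rep_len(seq_len(n_areas), n))
    tibble::tibble(
      station_id = sprintf("%s%02d", prefix, seq_len(n)),
      area_id = areas$area_id[host],
      x_km = areas$x_km[host] + rnorm(n, 0, 2),
      y_km = areas$y_km[host] + rnorm(n, 0, 2)
    )
  }
  pm_stations <- place_stations(config$n_pm_stations, "PM")
  met_stations <- place_stations(config$n_met_stations, "MET")

  ## ---- temperatures ------------------------------------------------------
  # coldest around mid-July (day 196): southern-hemisphere seasonality
  seasonal_tmean <- config$temp_annual_mean -
    config$temp_annual_amplitude * cos(2 * pi * (yday - 196) / 365.25)
  weather <- rnorm(n_days, 0, 2.5)           # shared synoptic anomaly

  area_off <- rnorm(n_areas, 0, 0.8)
  area_tmean <- outer(seasonal_tmean + weather, area_off, "+")  # days x areas
  area_hdd <- pmax(18 - area_tmean, 0)  # pmax(x, 0) keeps dim(x)

  met_off <- rnorm(config$n_met_stations, 0, 0.8)
  met_tmean <- outer(seasonal_tmean + weather, met_off, "+") +
    matrix(rnorm(n_days * config$n_met_stations, 0, 0.7),
           n_days, config$n_met_stations)
  half_range <- config$temp_daily_range / 2
  tmin <- met_tmean - half_range +
    matrix(rnorm(n_days * config$n_met_stations, 0, 0.5),
           n_days, config$n_met_stations)
  tmax <- met_tmean + half_range +
    matrix(rnorm(n_days * config$n_met_stations, 0, 0.5),
           n_days, config$n_met_stations)
  swap <- tmin > tmax
  if (any(swap)) { tmp <- tmin[swap]; tmin[swap] <- tmax[swap]; tmax[swap] <- tmp }
  met <- tibble::tibble(
    station_id = rep(met_stations$station_id, each = n_days),
    date = rep(dates, config$n_met_stations),
    tmin = as.vector(tmin),
    tmax = as.vector(tmax)
  )

  ## ---- wood-heater term (days x areas) -----------------------------------
  hdd_ref <- max(1, 18 - (config$temp_annual_mean - config$temp_annual_amplitude))
  area_factor <- runif(n_areas, 0.7, 1.3)
  winter <- month %in% 5:8
  transition <- month %in% c(3, 4, 9, 10)
  whs <- matrix(0, n_days, n_areas)
  base_whs <- sweep(area_hdd / hdd_ref, 2, area_factor, "*") *
    config$whs_winter_amplitude
  whs[winter, ] <- base_whs[winter, ]
  # cold transition days light up stochastically, with probability rising in
  # HDD: heater use is rare until days are genuinely cold (winter-like HDD)
  p_active <- stats::plogis((area_hdd - 9) / 1)
  act <- matrix(runif(n_days * n_areas), n_days, n_areas) < p_active
  whs[transition, ] <- (base_whs * act)[transition, ]

  ## ---- landscape-fire events (days x areas) ------------------------------
  lfs <- matrix(0, n_days, n_areas)
  season <- .summer_season(dates)
  dur_probs <- stats::dgeom(0:15, prob = 0.35)
  draw_events <- function(eligible_idx, rate, mag_scale, max_dur = 16) {
    if (length(eligible_idx) == 0) return(NULL)
    n_ev <- rpois(1, rate)
    if (n_ev == 0) return(NULL)
    out <- vector("list", n_ev)
    for (e in seq_len(n_ev)) {
      start <- sample(eligible_idx, 1)
      dur <- sample(1:max_dur, 1, prob = dur_probs[1:max_dur])
      idx <- start:min(start + dur - 1, n_days)
      mag <- rlnorm(1, log(mag_scale), config$lfs_magnitude_sdlog)
      out[[e]] <- list(idx = idx, mag = mag * runif(length(idx), 0.8, 1))
    }
    out
  }
  for (a in seq_len(n_areas)) {
    # summer bushfire seasons
    for (s in unique(season[month %in% c(11, 12, 1, 2)])) {
      elig <- which(season == s & month %in% c(11, 12, 1, 2))
      for (ev in draw_events(elig, config$lfs_event_rate,
                             config$lfs_event_magnitude) %||% list()) {
        lfs[ev$idx, a] <- pmax(lfs[ev$idx, a], ev$mag)
      }
    }
    # prescribed-burn windows in transition months, on low-HDD days only
    years <- unique(as.integer(format(dates, "%Y")))
    for (y in years) {
      for (mm in list(c(3, 4), c(9, 10))) {
        # burn windows need mild, heating-free weather
        elig <- which(as.integer(format(dates, "%Y")) == y &
                        month %in% mm & area_hdd[, a] < 4)
        for (ev in draw_events(elig, 0.6 * config$lfs_event_rate,
                               0.5 * config$lfs_event_magnitude,
                               max_dur = 4) %||% list()) {
          keep <- ev$idx[area_hdd[ev$idx, a] < 5]
          lfs[keep, a] <- pmax(lfs[keep, a], ev$mag[match(keep, ev$idx)])
        }
      }
    }
  }
  # a day carries one source: fires suppress the wood-heater term
  whs[lfs > 0] <- 0

  ## ---- truth -------------------------------------------------------------
  truth_attr <- whs + lfs
  truth_type <- matrix("unpolluted", n_days, n_areas)
  truth_type[whs > 0] <- "WHS"
  truth_type[lfs > 0] <- "LFS"
  truth <- tibble::tibble(
    area_id = rep(areas$area_id, each = n_days),
    date = rep(dates, n_areas),
    day_type_true = as.vector(truth_type),
    pm25_attributable_true = as.vector(truth_attr)
  )

  ## ---- hourly PM2.5 at stations ------------------------------------------
  # day-to-day background variation: mean-one lognormal per area-day, so
  # clean-day daily means average to background_mean
  s_bg <- sqrt(log(1 + config$background_cv^2))
  bg_day <- config$background_mean *
    matrix(rlnorm(n_days * n_areas, -s_bg^2 / 2, s_bg), n_days, n_areas)
  host <- match(pm_stations$area_id, areas$area_id)
  profile <- config$whs_diurnal_profile
  n_st <- config$n_pm_stations
  hourly <- vector("list", n_st)
  for (s in seq_len(n_st)) {
    a <- host[s]
    daily_whs <- whs[, a]
    daily_lfs <- lfs[, a]
    pm <- rep(bg_day[, a], each = 24) +
      rep(daily_whs, each = 24) * rep(profile, n_days) +
      rep(daily_lfs, each = 24) +
      rnorm(24 * n_days, 0, config$noise_sd)
    pm <- pmax(pm, 0.05)
    hourly[[s]] <- tibble::tibble(
      station_id = pm_stations$station_id[s],
      date = rep(dates, each = 24),
      hour = rep(0:23, n_days),
      pm25 = pm
    )
  }
  hourly <- dplyr::bind_rows(hourly)
  if (config$missing_hour_rate > 0) {
    hourly <- hourly[runif(nrow(hourly)) >= config$missing_hour_rate, ]
  }

  structure(list(
    areas = areas,
    pm_stations = pm_stations[, c("station_id", "x_km", "y_km")],
    met_stations = met_stations[, c("station_id", "x_km", "y_km")],
    hourly = hourly,
    met = met,
    truth = truth,
    baseline_rates = default_baseline_rates(),
    dates = dates,
    config = config
  ), class = "smoke_world")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.smoke_world <- function(x, ...) {
  cat("<smoke_world>", length(x$dates), "days,",
      nrow(x$areas), "areas,",
      nrow(x$pm_stations), "PM stations,",
      nrow(x$met_stations), "met stations\n")
  cat("  period:", format(min(x$dates)), "to", format(max(x$dates)),
      " seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic world to disk in the pipeline's input dialects
#'
#' Emits `hourly_pm25.csv` (station_id, ISO-8601 local timestamp, pm25),
#' `daily_met.csv`, `areas.geojson` (point centroids on a planar km grid,
#' with population and woodstove properties), `baseline_rates.csv`,
#' `truth.csv` and `config.yaml`. The files round-trip losslessly through
#' [read_world_inputs()].
#'
#' @param world A `smoke_world`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "smoke_world"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory: ", dir, call. = FALSE)
  }
  hourly <- world$hourly |>
    mutate(timestamp = sprintf("%sT%02d:00:00", format(.data$date), .data$hour)) |>
    select("station_id", "timestamp", "pm25")
  readr::write_csv(hourly, file.path(dir, "hourly_pm25.csv"))
  readr::write_csv(world$met, file.path(dir, "daily_met.csv"))
  readr::write_csv(world$baseline_rates, file.path(dir, "baseline_rates.csv"))
  readr::write_csv(world$truth, file.path(dir, "truth.csv"))
  readr::write_csv(world$pm_stations, file.path(dir, "pm_stations.csv"))
  readr::write_csv(world$met_stations, file.path(dir, "met_stations.csv"))

  features <- lapply(seq_len(nrow(world$areas)), function(i) {
    a <- world$areas[i, ]
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(a$x_km, a$y_km)),
      properties = list(
        area_id = a$area_id, region_id = a$region_id,
        population = a$population, pop_0_17 = a$pop_0_17,
        pop_18_64 = a$pop_18_64, pop_65plus = a$pop_65plus,
        pop_30plus = a$pop_30plus, woodstoves = a$woodstoves
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file.path(dir, "areas.geojson"),
                       auto_unbox = TRUE, digits = NA)

  cfg <- world$config
  yaml::write_yaml(list(
    seed = cfg$seed,
    start_date = format(cfg$start_date), end_date = format(cfg$end_date),
    n_areas = cfg$n_areas, n_pm_stations = cfg$n_pm_stations,
    n_met_stations = cfg$n_met_stations,
    background_mean = cfg$background_mean,
    whs_winter_amplitude = cfg$whs_winter_amplitude,
    lfs_event_rate = cfg$lfs_event_rate,
    lfs_event_magnitude = cfg$lfs_event_magnitude,
    noise_sd = cfg$noise_sd
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read pipeline inputs from a directory written by [write_world()]
#'
#' The same dialects are accepted for real monitor exports: hourly PM2.5
#' with ISO-8601 timestamps, daily min/max temperatures, a point GeoJSON of
#' area centroids, and CSV baseline rates. `truth.csv` is read when present
#' (synthetic worlds only).
#'
#' @param dir Directory containing the input files.
#' @return A list with `hourly`, `met`, `areas`, `pm_stations`,
#'   `met_stations`, `baseline_rates` and (if present) `truth`.
#' @export
read_world_inputs <- function(dir) {
  hourly <- readr::read_csv(file.path(dir, "hourly_pm25.csv"),
                            col_types = readr::cols(
                              station_id = "c", timestamp = "c", pm25 = "d"))
  hourly <- hourly |>
    mutate(date = as.Date(substr(.data$timestamp, 1, 10)),
           hour = as.integer(substr(.data$timestamp, 12, 13))) |>
    select("station_id", "date", "hour", "pm25")
  met <- readr::read_csv(file.path(dir, "daily_met.csv"),
                         col_types = readr::cols(station_id = "c", date = "D",
                                                 tmin = "d", tmax = "d"))
  gj <- jsonlite::read_json(file.path(dir, "areas.geojson"))
  areas <- purrr::map_dfr(gj$features, function(f) {
    p <- f$properties
    tibble::tibble(
      area_id = p$area_id, region_id = p$region_id,
      x_km = f$geometry$coordinates[[1]], y_km = f$geometry$coordinates[[2]],
      population = p$population, pop_0_17 = p$pop_0_17,
      pop_18_64 = p$pop_18_64, pop_65plus = p$pop_65plus,
      pop_30plus = p$pop_30plus, woodstoves = p$woodstoves
    )
  })
  out <- list(
    hourly = hourly, met = met, areas = areas,
    pm_stations = readr::read_csv(file.path(dir, "pm_stations.csv"),
                                  col_types = "cdd"),
    met_stations = readr::read_csv(file.path(dir, "met_stations.csv"),
                                   col_types = "cdd"),
    baseline_rates = readr::read_csv(file.path(dir, "baseline_rates.csv"),
                                     col_types = "ccd")
  )
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- readr::read_csv(truth_path, col_types = readr::cols(
      area_id = "c", date = "D", day_type_true = "c",
      pm25_attributable_true = "d"))
  }
  out
}
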