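#' Valid daily mean PM2.5 per station
#'
#' Collapses hourly records to daily means under the validity rule: an hour
#' is valid when its concentration is strictly positive, and a daily mean
#' is reported only when at least `min_valid_hours` valid hours are
#' available that day; otherwise the mean is missing. Zero readings are
#' treated as invalid hours, not as zeros.
#'
#' @param hourly Tibble with columns `station_id`, `date`, `hour`, `pm25`.
#' @param min_valid_hours Minimum count of valid hours (default 18).
#' @return Tibble `station_id`, `date`, `pm25_mean`, `n_valid_hours`.
#' @export
daily_station_means <- function(hourly, min_valid_hours = 18) {
  stopifnot(all(c("station_id", "date", "pm25") %in% names(hourly)))
  hourly |>
    group_by(.data$station_id, .data$date) |>
    summarise(
      n_valid_hours = sum(is.finite(.data$pm25) & .data$pm25 > 0),
      pm25_mean = ifelse(
        .data$n_valid_hours >= min_valid_hours,
        mean(.data$pm25[is.finite(.data$pm25) & .data$pm25 > 0]),
        NA_real_),
      .groups = "drop")
}

#' Heating degree days
#'
#' Degrees Celsius by which the daily mean temperature, `(tmin + tmax)/2`,
#' falls short of a comfort temperature; floored at zero. Larger values
#' indicate colder days and higher residential heating demand.
#'
#' @param tmin,tmax Daily minimum and maximum temperature (deg C); vectors.
#' @param comfort Comfort temperature (deg C), default 18.
#' @return Numeric vector of heating degree days (deg C-days), >= 0.
#' @export
heating_degree_days <- function(tmin, tmax, comfort = 18) {
  bad <- !is.na(tmin) & !is.na(tmax) & tmin > tmax
  if (any(bad)) {
    stop("tmin exceeds tmax for ", sum(bad), " record(s)", call. = FALSE)
  }
  pmax(0, comfort - (tmin + tmax) / 2)
}

#' Inverse-distance-weighted interpolation at a point
#'
#' Weighted mean of station values with weights `d^(-power)` over stations
#' within `radius_km` of the target that carry a non-missing value. A
#' station closer than `eps_km` (1 m by default) to the target returns its
#' own value directly. Returns `NA` when no station qualifies.
#'
#' @param station_xy Two-column matrix (km) of station coordinates.
#' @param values Numeric vector of station values (NA = missing today).
#' @param target_xy Length-2 numeric target coordinate (km).
#' @param radius_km Search radius (km), default 100.
#' @param power Distance-decay exponent, default 2.
#' @param eps_km Coincidence tolerance (km), default 0.001.
#' @return Interpolated value, or `NA_real_`.
#' @export
idw_interpolate <- function(station_xy, values, target_xy,
                            radius_km = 100, power = 2, eps_km = 0.001) {
  station_xy <- matrix(as.numeric(station_xy), ncol = 2)
  stopifnot(length(values) == nrow(station_xy), radius_km > 0)
  d <- sqrt((station_xy[, 1] - target_xy[1])^2 +
              (station_xy[, 2] - target_xy[2])^2)
  ok <- is.finite(values) & d <= radius_km
  if (!any(ok)) return(NA_real_)
  d <- d[ok]; v <- values[ok]
  if (any(d < eps_km)) return(v[which.min(d)])
  w <- d^(-power)
  sum(w * v) / sum(w)
}

# weight matrix areas x stations; zero outside radius, distances capped at
# eps so coincident stations do not produce infinite weights
.idw_weights <- function(areas, stations, radius_km, power, eps_km = 0.001) {
  dx <- outer(areas$x_km, stations$x_km, "-")
  dy <- outer(areas$y_km, stations$y_km, "-")
  d <- sqrt(dx^2 + dy^2)
  w <- pmax(d, eps_km)^(-power)
  w[d > radius_km] <- 0
  attr(w, "coincident") <- d < eps_km
  w
}

# interpolate one variable: values is a stations x days matrix with NAs
.idw_field <- function(w, values) {
  fin <- is.finite(values)
  v0 <- ifelse(fin, values, 0)
  numer <- w %*% v0
  denom <- w %*% fin
  out <- numer / denom
  out[denom == 0] <- NA_real_
  # exact pass-through where a station sits on the centroid and has a value
  co <- attr(w, "coincident")
  if (any(co)) {
    for (a in which(rowSums(co) > 0)) {
      s <- which(co[a, ])[1]
      have <- fin[s, ]
      out[a, have] <- values[s, have]
    }
  }
  out
}

#' Build the area-day exposure table
#'
#' Interpolates daily PM2.5, heating degree days and min/max temperature
#' from stations to every area centroid by inverse distance weighting
#' within a fixed radius. HDD is computed at the met stations from their
#' own temperatures and then interpolated, rather than being recomputed
#' from interpolated temperatures. One row is emitted per area and date;
#' area-days with no qualifying PM station carry a missing `pm25` and are
#' excluded downstream.
#'
#' @param daily_pm Output of [daily_station_means()].
#' @param pm_stations Tibble `station_id`, `x_km`, `y_km`.
#' @param met Tibble `station_id`, `date`, `tmin`, `tmax`.
#' @param met_stations Tibble `station_id`, `x_km`, `y_km`.
#' @param areas Area table with `area_id`, `x_km`, `y_km`.
#' @param radius_km Interpolation radius (km), default 100.
#' @param power IDW exponent, default 2.
#' @param comfort Comfort temperature for HDD (deg C), default 18.
#' @return Tibble `area_id`, `date`, `pm25`, `hdd`, `tmin`, `tmax`,
#'   `n_contributing_stations`.
#' @export
build_area_days <- function(daily_pm, pm_stations, met, met_stations, areas,
                            radius_km = 100, power = 2, comfort = 18) {
  stopifnot(nrow(daily_pm) > 0, nrow(met) > 0, nrow(areas) > 0)
  dates <- sort(unique(c(daily_pm$date, met$date)))
  to_matrix <- function(df, stations, col) {
    m <- matrix(NA_real_, nrow(stations), length(dates),
                dimnames = list(stations$station_id, NULL))
    i <- match(df$station_id, stations$station_id)
    j <- match(as.integer(df$date), as.integer(dates))
    keep <- !is.na(i) & !is.na(j)
    m[cbind(i[keep], j[keep])] <- df[[col]][keep]
    m
  }
  met <- met |> mutate(hdd = heating_degree_days(.data$tmin, .data$tmax, comfort))

  w_pm <- .idw_weights(areas, pm_stations, radius_km, power)
  w_met <- .idw_weights(areas, met_stations, radius_km, power)

  pm_m <- to_matrix(daily_pm, pm_stations, "pm25_mean")
  pm_i <- .idw_field(w_pm, pm_m)
  n_contrib <- (w_pm > 0) %*% is.finite(pm_m)
  hdd_i <- .idw_field(w_met, to_matrix(met, met_stations, "hdd"))
  tmin_i <- .idw_field(w_met, to_matrix(met, met_stations, "tmin"))
  tmax_i <- .idw_field(w_met, to_matrix(met, met_stations, "tmax"))

  out <- tibble::tibble(
    area_id = rep(areas$area_id, times = length(dates)),
    date = rep(dates, each = nrow(areas)),
    pm25 = as.vector(pm_i),
    hdd = as.vector(hdd_i),
    tmin = as.vector(tmin_i),
    tmax = as.vector(tmax_i),
    n_contributing_stations = as.integer(n_contrib)
  )
  frac_missing <- out |>
    group_by(.data$area_id) |>
    summarise(f = mean(is.na(.data$pm25)), .groups = "drop") |>
    filter(.data$f > 0.5)
  if (nrow(frac_missing) > 0) {
    warning("areas with no in-radius PM station for >50% of days: ",
            paste(frac_missing$area_id, collapse = ", "), call. = FALSE)
  }
  out
}
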