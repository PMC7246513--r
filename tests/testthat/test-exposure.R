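make_hourly <- function(pm, station = "S1", date = as.Date("2017-06-01")) {
  tibble::tibble(station_id = station, date = date,
                 hour = seq_along(pm) - 1, pm25 = pm)
}

test_that("daily means follow the 18-valid-hour rule with zeros invalid", {
  expect_equal(daily_station_means(make_hourly(rep(5, 24)))$pm25_mean, 5)
  # 17 valid hours: no daily mean
  expect_true(is.na(daily_station_means(make_hourly(rep(2, 17)))$pm25_mean))
  # 18 valid hours at 2 plus 6 zero hours: zeros are invalid, mean stays 2
  d <- daily_station_means(make_hourly(c(rep(2, 18), rep(0, 6))))
  expect_equal(d$n_valid_hours, 18)
  expect_equal(d$pm25_mean, 2)
  # 24 zero hours: no valid hours at all
  expect_true(is.na(daily_station_means(make_hourly(rep(0, 24)))$pm25_mean))
})

test_that("heating degree days match the comfort-shortfall definition", {
  expect_equal(heating_degree_days(10, 20), 3)
  expect_equal(heating_degree_days(18, 18), 0)
  expect_equal(heating_degree_days(20, 30), 0)
  expect_error(heating_degree_days(21, 20), "tmin exceeds tmax")
  # non-increasing in each temperature, zero at/above comfort
  t <- seq(-5, 30, by = 0.5)
  h <- heating_degree_days(t, t + 5)
  expect_true(all(diff(h) <= 0))
  expect_true(all(h[(t + t + 5) / 2 >= 18] == 0))
})

test_that("IDW reproduces direct formula evaluation", {
  xy <- matrix(c(0, 0), ncol = 2)
  expect_equal(idw_interpolate(xy, 7.7, c(3, 4)), 7.7)
  xy2 <- matrix(c(-1, 0, 1, 0), ncol = 2, byrow = TRUE)
  expect_equal(idw_interpolate(xy2, c(2, 4), c(0, 0)), 3)
  # brute-force oracle at arbitrary positions
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    xy <- matrix(runif(2 * n, -50, 50), ncol = 2)
    v <- runif(n, 0, 30)
    tgt <- runif(2, -50, 50)
    d <- sqrt((xy[, 1] - tgt[1])^2 + (xy[, 2] - tgt[2])^2)
    oracle <- sum(d^(-2) * v) / sum(d^(-2))
    expect_equal(idw_interpolate(xy, v, tgt), oracle, tolerance = 1e-12)
    # convex combination: bounded by contributing extremes
    expect_gte(idw_interpolate(xy, v, tgt), min(v))
    expect_lte(idw_interpolate(xy, v, tgt), max(v))
  }
})

test_that("IDW respects the radius, missing values and coincident stations", {
  xy <- matrix(c(0, 0, 101, 0), ncol = 2, byrow = TRUE)
  expect_equal(idw_interpolate(xy, c(5, 500), c(0, 1)), 5)
  expect_true(is.na(idw_interpolate(matrix(c(101, 0), ncol = 2), 5, c(0, 0))))
  expect_true(is.na(idw_interpolate(xy, c(NA, NA), c(0, 1))))
  # coincident station returns its own value exactly
  xy3 <- matrix(c(10, 10, 12, 10), ncol = 2, byrow = TRUE)
  expect_identical(idw_interpolate(xy3, c(3.3, 9.9), c(10, 10)), 3.3)
  # shrinking the radius never adds stations: value moves toward near station
  v <- c(1, 100)
  wide <- idw_interpolate(xy3, v, c(10.5, 10), radius_km = 100)
  narrow <- idw_interpolate(xy3, v, c(10.5, 10), radius_km = 1)
  expect_equal(narrow, 1)
  expect_gt(wide, narrow)
})

test_that("area-day construction passes through a single in-radius station", {
  w <- generate_world(generator_config(
    n_areas = 1, n_pm_stations = 1, n_met_stations = 1,
    start_date = "2017-06-01", end_date = "2017-06-30", seed = 3))
  daily <- daily_station_means(w$hourly)
  ad <- build_area_days(daily, w$pm_stations, w$met, w$met_stations, w$areas)
  j <- dplyr::inner_join(ad, daily, by = "date")
  expect_equal(j$pm25, j$pm25_mean)
  expect_true(all(j$n_contributing_stations == 1))
  # HDD interpolated from the station equals the station's own HDD
  expect_equal(j$hdd,
               heating_degree_days(w$met$tmin, w$met$tmax)[match(j$date, w$met$date)])
})

test_that("stations beyond the interpolation radius never contribute", {
  areas <- tibble::tibble(area_id = "A01", x_km = 0, y_km = 0)
  far <- tibble::tibble(station_id = "PM1", x_km = 150, y_km = 0)
  daily <- tibble::tibble(station_id = "PM1", date = as.Date("2017-06-01"),
                          pm25_mean = 9, n_valid_hours = 24)
  met <- tibble::tibble(station_id = "MET1", date = as.Date("2017-06-01"),
                        tmin = 5, tmax = 15)
  met_st <- tibble::tibble(station_id = "MET1", x_km = 0, y_km = 1)
  expect_warning(
    ad <- build_area_days(daily, far, met, met_st, areas),
    "no in-radius PM station")
  expect_true(is.na(ad$pm25))
  expect_equal(ad$n_contributing_stations, 0L)
  expect_equal(ad$hdd, 8)
})

test_that("fast interpolation surface agrees with per-point IDW", {
  w <- small_world()
  daily <- daily_station_means(w$hourly)
  ad <- small_area_days()
  set.seed(19)
  some_days <- sample(unique(ad$date), 5)
  for (d in as.list(some_days)) {
    day_vals <- daily[daily$date == d, ]
    v <- day_vals$pm25_mean[match(w$pm_stations$station_id,
                                  day_vals$station_id)]
    for (a in seq_len(nrow(w$areas))) {
      expected <- idw_interpolate(
        cbind(w$pm_stations$x_km, w$pm_stations$y_km), v,
        c(w$areas$x_km[a], w$areas$y_km[a]))
      got <- ad$pm25[ad$area_id == w$areas$area_id[a] & ad$date == d]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
})
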