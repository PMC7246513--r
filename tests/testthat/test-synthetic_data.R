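test_that("worlds with no injected source are entirely unpolluted", {
  w <- generate_world(generator_config(
    n_areas = 3, n_pm_stations = 3, n_met_stations = 3,
    start_date = "2017-01-01", end_date = "2017-12-31",
    whs_winter_amplitude = 0, lfs_event_rate = 0, seed = 2))
  expect_true(all(w$truth$day_type_true == "unpolluted"))
  expect_true(all(w$truth$pm25_attributable_true == 0))
})

test_that("zero fire rate leaves summer free of true fire days", {
  w <- generate_world(generator_config(
    n_areas = 3, n_pm_stations = 3, n_met_stations = 3,
    start_date = "2017-01-01", end_date = "2017-12-31",
    lfs_event_rate = 0, seed = 2))
  m <- as.integer(format(w$truth$date, "%m"))
  expect_false(any(w$truth$day_type_true == "LFS" & m %in% c(11, 12, 1, 2)))
})

test_that("winter PM2.5 exceeds summer PM2.5 at every station under defaults", {
  w <- generate_world(generator_config(seed = 1))
  monthly <- w$hourly |>
    dplyr::mutate(m = format(date, "%m")) |>
    dplyr::filter(m %in% c("01", "07")) |>
    dplyr::group_by(station_id, m) |>
    dplyr::summarise(pm = mean(pm25), .groups = "drop") |>
    tidyr::pivot_wider(names_from = m, values_from = pm)
  expect_true(all(monthly$`07` > monthly$`01`))
})

test_that("a fixed seed reproduces the world exactly", {
  cfg <- generator_config(n_areas = 3, n_pm_stations = 3, n_met_stations = 3,
                          start_date = "2017-06-01", end_date = "2017-08-31",
                          seed = 5)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$hourly, w2$hourly)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$areas, w2$areas)
})

test_that("truth labels partition area-days and attributable PM is coherent", {
  w <- small_world()
  expect_true(all(w$truth$day_type_true %in% c("unpolluted", "WHS", "LFS")))
  expect_equal(nrow(w$truth), nrow(w$areas) * length(w$dates))
  expect_true(all(w$truth$pm25_attributable_true >= 0))
  unpol <- w$truth$day_type_true == "unpolluted"
  expect_true(all(w$truth$pm25_attributable_true[unpol] == 0))
  expect_true(all(w$truth$pm25_attributable_true[!unpol] > 0))
})

test_that("fire events are rarer but more extreme than wood-heater days", {
  tr <- recovery_world()$truth
  lfs <- tr$pm25_attributable_true[tr$day_type_true == "LFS"]
  whs <- tr$pm25_attributable_true[tr$day_type_true == "WHS"]
  expect_lt(length(lfs), length(whs))
  expect_gt(max(lfs), max(whs))
  expect_gt(stats::sd(lfs), stats::sd(whs))
})

test_that("noise-free daily station means equal background plus truth source", {
  w <- generate_world(generator_config(
    n_areas = 3, n_pm_stations = 3, n_met_stations = 3,
    start_date = "2017-01-01", end_date = "2017-12-31",
    noise_sd = 0, background_cv = 0, missing_hour_rate = 0, seed = 9))
  daily <- daily_station_means(w$hourly)
  # recover each station's host area as the nearest area centroid
  host <- sapply(seq_len(nrow(w$pm_stations)), function(i) {
    d <- sqrt((w$areas$x_km - w$pm_stations$x_km[i])^2 +
                (w$areas$y_km - w$pm_stations$y_km[i])^2)
    w$areas$area_id[which.min(d)]
  })
  daily$area_id <- host[match(daily$station_id, w$pm_stations$station_id)]
  j <- dplyr::inner_join(daily, w$truth, by = c("area_id", "date"))
  expect_equal(j$pm25_mean - w$config$background_mean,
               j$pm25_attributable_true, tolerance = 1e-12)
})

test_that("write_world/read_world_inputs round-trips losslessly", {
  w <- generate_world(generator_config(
    n_areas = 3, n_pm_stations = 3, n_met_stations = 3,
    start_date = "2017-02-01", end_date = "2017-03-31", seed = 4))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  back <- read_world_inputs(dir)
  expect_equal(as.data.frame(back$hourly), as.data.frame(w$hourly))
  expect_equal(as.data.frame(back$met), as.data.frame(w$met))
  expect_equal(as.data.frame(back$truth), as.data.frame(w$truth))
  expect_equal(as.data.frame(back$areas), as.data.frame(w$areas))
  expect_equal(nrow(back$truth), 3 * 59)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(start_date = "2018-01-01",
                                end_date = "2017-01-01"), "date range")
  expect_error(generator_config(n_pm_stations = 0), "at least one")
  expect_error(generator_config(noise_sd = -1), ">= 0")
  expect_error(generator_config(whs_diurnal_profile = rep(1, 12)), "24")
})
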