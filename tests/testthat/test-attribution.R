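series <- function(pm, start = "2016-01-01") {
  tibble::tibble(area_id = "A01",
                 date = seq(as.Date(start), by = "day",
                            length.out = length(pm)),
                 pm25 = pm)
}

test_that("season scheme validates and partitions the year", {
  s <- season_scheme()
  expect_setequal(c(s$winter, s$summer, s$transition), 1:12)
  expect_equal(s$transition, c(3, 4, 9, 10))
  expect_error(season_scheme(5:9, 9:12), "disjoint")
  expect_error(season_scheme(0:3, 6:7), "1..12")
})

test_that("fire days come from a strict percentile exceedance", {
  # constant series: nothing exceeds its own percentile
  expect_length(identify_fire_days(series(rep(3, 400))), 0)
  # one extreme summer day is picked up
  pm <- rep(2, 400)
  pm[350] <- 200  # 2016-12-15, summer
  fd <- identify_fire_days(series(pm))
  expect_equal(fd, as.Date("2016-12-15"))
  # brute-force percentile oracle on an arbitrary 40-value series
  set.seed(8)
  pm <- stats::rlnorm(40, 1, 0.8)
  s40 <- series(pm, start = "2016-11-01")  # all summer (Nov 1 - Dec 10)
  for (p in c(75, 90, 95)) {
    srt <- sort(pm)
    h <- (40 - 1) * p / 100
    thr <- srt[floor(h) + 1] +
      (h - floor(h)) * (srt[floor(h) + 2] - srt[floor(h) + 1])
    expect_setequal(identify_fire_days(s40, percentile = p, min_history = 20),
                    s40$date[pm > thr])
  }
  expect_error(identify_fire_days(series(rep(2, 10))), "insufficient")
})

test_that("raising the percentile never adds fire days", {
  set.seed(12)
  s <- series(stats::rlnorm(730, 0.5, 1))
  counts <- sapply(c(75, 90, 95, 99), function(p)
    length(identify_fire_days(s, percentile = p)))
  expect_true(all(diff(counts) <= 0))
})

test_that("counterfactual is the fire-day-excluded summer mean", {
  s <- series(rep(1.4, 365))
  expect_equal(compute_counterfactual(s, as.Date(character(0))), 1.4)
  pm <- rep(10, 400); m <- as.integer(format(series(pm)$date, "%m"))
  pm[m %in% c(11, 12, 1, 2)] <- 2
  fire <- series(pm)$date[m == 12][1]
  pm[series(pm)$date == fire] <- 200
  expect_equal(compute_counterfactual(series(pm), fire), 2)
  # never exceeds the summer maximum
  set.seed(3)
  s2 <- series(stats::rlnorm(400, 1, 1))
  m2 <- as.integer(format(s2$date, "%m"))
  expect_lte(compute_counterfactual(s2, as.Date(character(0))),
             max(s2$pm25[m2 %in% c(11, 12, 1, 2)]))
  expect_error(compute_counterfactual(series(rep(NA_real_, 400)),
                                      as.Date(character(0))), "no valid")
})

test_that("attribution splits days at the counterfactual", {
  a <- attribute_pm(c(1.4, 7.7, 0.5), 1.4)
  expect_equal(a$polluted, c(FALSE, TRUE, FALSE))
  expect_equal(a$pm25_attributable, c(0, 6.3, 0))
})

test_that("seasonal labels follow the winter/summer/transition rule", {
  d <- tibble::tibble(
    date = as.Date(c("2017-06-15", "2017-01-15", "2017-04-15", "2017-06-16")),
    polluted = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(label_seasonal(d),
               c("WHS", "LFS", NA, "unpolluted"))
})

test_that("classifier separates sources and fails safely on degenerate input", {
  cl <- small_classified()
  clf <- attr(cl, "classifier")
  expect_gte(clf$holdout_accuracy, 0.9)
  # single-class training set is an error
  lab <- cl |> dplyr::filter(label_origin == "rule_season")
  expect_error(train_transition_classifier(
    lab |> dplyr::filter(day_type == "WHS")), "both WHS and LFS")
  expect_error(train_transition_classifier(
    lab |> dplyr::mutate(day_type = "fog")), "WHS or LFS")
  # empty prediction set is fine
  expect_length(predict_transition_sources(clf, lab[0, ]), 0)
  expect_error(predict_transition_sources(clf, lab |> dplyr::select(-"hdd")),
               "missing feature columns")
})

test_that("permuted training labels give chance-level holdout accuracy", {
  lab <- small_classified() |>
    dplyr::filter(label_origin == "rule_season")
  set.seed(21)
  lab$day_type <- sample(lab$day_type)
  fit <- train_transition_classifier(lab, seed = 21)
  # with the signal destroyed, accuracy collapses to the majority-class
  # share (the classes are not balanced), far below the real fit
  majority <- max(prop.table(table(lab$day_type)))
  expect_lt(abs(fit$holdout_accuracy - majority), 0.10)
  real <- attr(small_classified(), "classifier")$holdout_accuracy
  expect_gt(real - fit$holdout_accuracy, 0.2)
})

test_that("classification partitions area-days with coherent attribution", {
  cl <- small_classified()
  expect_true(all(cl$day_type %in% c("unpolluted", "WHS", "LFS")))
  expect_true(all(cl$pm25_attributable >= 0))
  unpol <- cl$day_type == "unpolluted"
  expect_true(all(cl$pm25_attributable[unpol] == 0))
  expect_true(all(cl$pm25_attributable[!unpol] > 0))
  expect_equal(cl$pm25_attributable[!unpol],
               (cl$pm25 - cl$counterfactual)[!unpol])
  # predictions only happen in transition months
  m <- as.integer(format(cl$date, "%m"))
  expect_true(all(m[cl$label_origin == "predicted"] %in% c(3, 4, 9, 10)))
  # season-rule labels match their season
  expect_true(all(m[cl$label_origin == "rule_season" & cl$day_type == "WHS"]
                  %in% 5:8))
  expect_true(all(m[cl$label_origin == "rule_season" & cl$day_type == "LFS"]
                  %in% c(11, 12, 1, 2)))
})

test_that("day-type summary covers all days and sums to 100%", {
  cl <- small_classified()
  s <- summarize_day_types(cl)
  expect_equal(sum(s$share_pct), 100)
  expect_true(all(s$max_pm25 >= s$mean_pm25))
  # an all-unpolluted world summarizes to a single 100% row
  quiet <- cl |> dplyr::mutate(day_type = "unpolluted")
  sq <- summarize_day_types(quiet)
  expect_equal(nrow(sq), 1)
  expect_equal(sq$share_pct, 100)
})
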