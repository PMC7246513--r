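test_that("the case equation matches independent arithmetic", {
  # direct evaluation of IR x Pop x (exp(beta dC) - 1)
  expect_equal(attributable_cases(0.001, 10000, 0.001222, 20),
               0.001 * 10000 * (exp(0.001222 * 20) - 1), tolerance = 1e-12)
  expect_equal(attributable_cases(0.01, 5000, 0.006015, 0), 0)
  expect_error(attributable_cases(-0.1, 1, 0.001, 1), ">= 0")
  expect_error(attributable_cases(0.1, 1, 0.001, NA), "finite")
})

test_that("confidence bounds are beta +/- 1.96 se, floored at zero", {
  ci <- ci_betas(0.006015, 0.001034)
  expect_equal(ci$beta_lo, 0.006015 - 1.96 * 0.001034)
  expect_equal(ci$beta_hi, 0.006015 + 1.96 * 0.001034)
  expect_equal(ci_betas(0.5, 0), tibble::tibble(beta_lo = 0.5, beta_hi = 0.5))
  expect_equal(ci_betas(0.001, 0.01)$beta_lo, 0)
  expect_gt(ci_betas(0.001222, 0.000393)$beta_lo, 0)
})

test_that("linearized and exact case counts agree within 1% for small doses", {
  set.seed(5)
  for (i in 1:50) {
    beta <- runif(1, 1e-4, 5e-3)
    dc <- runif(1, 0, 0.0099 / beta)
    exact <- attributable_cases(0.01, 1e4, beta, dc)
    linear <- 0.01 * 1e4 * beta * dc
    if (exact > 0) expect_lt(abs(exact - linear) / exact, 0.01)
  }
})

test_that("cases are monotone in rate, population, coefficient and dose", {
  base <- attributable_cases(0.01, 1e4, 0.002, 5)
  expect_gt(attributable_cases(0.02, 1e4, 0.002, 5), base)
  expect_gt(attributable_cases(0.01, 2e4, 0.002, 5), base)
  expect_gt(attributable_cases(0.01, 1e4, 0.004, 5), base)
  expect_gt(attributable_cases(0.01, 1e4, 0.002, 10), base)
  # convexity: splitting a dose over two days yields fewer cases
  expect_lt(attributable_cases(0.01, 1e4, 0.002, 5) +
              attributable_cases(0.01, 1e4, 0.002, 7),
            attributable_cases(0.01, 1e4, 0.002, 12))
})

test_that("chronic WHS mortality matches the closed form on a toy year", {
  cl <- toy_classified(n_whs = 40, attr = 5)
  burden <- whs_mortality_burden(cl, toy_areas())
  expect_equal(nrow(burden), 1)
  delta_c <- 40 * 5 / 365
  expect_equal(burden$delta_c, delta_c, tolerance = 1e-12)
  expect_equal(burden$cases,
               0.0125 * 6200 * (exp(0.006015 * delta_c) - 1),
               tolerance = 1e-9)
  expect_equal(burden$cases_lo,
               0.0125 * 6200 * (exp((0.006015 - 1.96 * 0.001034) * delta_c) - 1),
               tolerance = 1e-9)
  expect_true(burden$cases_lo <= burden$cases & burden$cases <= burden$cases_hi)
  # doubling the attributable concentration is supra-linear
  twice <- whs_mortality_burden(toy_classified(n_whs = 40, attr = 10),
                                toy_areas())
  expect_gt(twice$cases, 2 * burden$cases)
})

test_that("short-term burden applies the right coefficient set per source", {
  dates <- as.Date(c("2017-01-10", "2017-06-10"))
  cl <- tibble::tibble(
    area_id = "A01", date = dates, pm25 = 11.4, hdd = c(0, 10),
    tmin = 10, tmax = 20, day_type = c("LFS", "WHS"),
    pm25_attributable = 10, label_origin = "rule_season",
    counterfactual = 1.4)
  b <- short_term_burden(cl, toy_areas())
  lfs <- b[b$source == "LFS", ]
  whs <- b[b$source == "WHS", ]
  # LFS: mortality + cvd + rsp + 3 asthma bands; WHS: cvd + rsp + 2 bands
  expect_setequal(
    paste(lfs$outcome, lfs$age_group),
    c("all_cause_mortality all", "cvd_admission all", "rsp_admission all",
      "asthma_ed 0_17", "asthma_ed 18_64", "asthma_ed 65plus"))
  expect_setequal(
    paste(whs$outcome, whs$age_group),
    c("cvd_admission all", "rsp_admission all",
      "asthma_ed 0_17", "asthma_ed 18_64"))
  # the elderly asthma row uses the strong fire coefficient
  eld <- lfs[lfs$outcome == "asthma_ed" & lfs$age_group == "65plus", ]
  expect_equal(eld$cases, (0.0025 / 365) * 1800 * (exp(0.013994 * 10) - 1),
               tolerance = 1e-9)
  # unpolluted days contribute no rows
  expect_equal(nrow(short_term_burden(
    dplyr::mutate(cl, day_type = "unpolluted"), toy_areas())), 0)
})

test_that("aggregation is additive and preserves interval ordering", {
  imp <- tibble::tibble(
    source = c("WHS", "WHS", "LFS"), outcome = "cvd_admission",
    cases = c(1, 2, 3), cases_lo = c(0.5, 1, 2), cases_hi = c(2, 3, 4))
  one <- aggregate_impacts(imp[1, ])
  expect_equal(one$cases, 1)
  by_src <- aggregate_impacts(imp, by = "source")
  tot <- aggregate_impacts(imp, by = "outcome")
  expect_equal(sum(by_src$cases), tot$cases)
  expect_true(all(by_src$cases_lo <= by_src$cases &
                    by_src$cases <= by_src$cases_hi))
})

test_that("dose-response defaults satisfy their structural invariants", {
  drf <- default_dose_response()
  expect_true(all(drf$beta > 0) && all(drf$se > 0))
  annual <- drf[drf$exposure_window == "annual", ]
  expect_equal(nrow(annual), 1)
  expect_equal(annual$outcome, "all_cause_mortality")
  expect_equal(annual$smoke_type, "WHS")
})
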