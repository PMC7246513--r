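#' Default dose-response function table
#'
#' Log-linear concentration-response coefficients (per ug/m3 PM2.5) with
#' standard errors, by health outcome, age band, smoke source and exposure
#' window, as used in the published Tasmanian biomass-smoke assessment this
#' pipeline implements: WHO-recommended coefficients for all-cause
#' mortality and cardiorespiratory admissions, and meta-analytic estimates
#' for asthma emergency-department visits. Long-term (annual) exposure
#' applies only to wood-heater smoke mortality; all other rows use daily
#' exposure. `smoke_type = "both"` rows apply to WHS and LFS days alike.
#'
#' @return Tibble with `outcome`, `age_group`, `smoke_type`,
#'   `exposure_window`, `beta`, `se`.
#' @export
default_dose_response <- function() {
  tibble::tribble(
    ~outcome,              ~age_group, ~smoke_type, ~exposure_window, ~beta,    ~se,
    "all_cause_mortality", "30plus",   "WHS",       "annual",         0.006015, 0.001034,
    "all_cause_mortality", "all",      "LFS",       "daily",          0.001222, 0.000393,
    "cvd_admission",       "all",      "both",      "daily",          0.000906, 0.000377,
    "rsp_admission",       "all",      "both",      "daily",          0.001882, 0.001051,
    "asthma_ed",           "0_17",     "WHS",       "daily",          0.003537, 0.000862,
    "asthma_ed",           "18_64",    "WHS",       "daily",          0.001686, 0.000527,
    "asthma_ed",           "0_17",     "LFS",       "daily",          0.003811, 0.001865,
    "asthma_ed",           "18_64",    "LFS",       "daily",          0.007071, 0.001586,
    "asthma_ed",           "65plus",   "LFS",       "daily",          0.013994, 0.002356
  )
}

#' Attributable cases from the log-linear risk model
#'
#' Expected case count `IR x Pop x (exp(beta x dC) - 1)`, where IR is the
#' baseline incidence rate over the exposure window, Pop the exposed
#' population, beta the concentration-response coefficient and dC the
#' attributable PM2.5. For small `beta x dC` this approaches the linear
#' form `IR x Pop x beta x dC`.
#'
#' @param ir Baseline incidence rate (cases per person per window).
#' @param pop Exposed population.
#' @param beta Coefficient (per ug/m3).
#' @param delta_c Attributable concentration (ug/m3).
#' @return Expected cases (vectorized).
#' @export
attributable_cases <- function(ir, pop, beta, delta_c) {
  vals <- c(ir, pop, beta, delta_c)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("ir, pop, beta and delta_c must be finite and >= 0", call. = FALSE)
  }
  ir * pop * expm1(beta * delta_c)
}

#' 95% confidence bounds for a coefficient
#'
#' `beta +/- 1.96 x se`, with the lower bound floored at zero; plugging
#' these into the case equation propagates coefficient uncertainty to the
#' impact estimates.
#'
#' @param beta Coefficient(s).
#' @param se Standard error(s), > 0 (a zero se collapses the interval).
#' @return Tibble with `beta_lo`, `beta_hi`.
#' @export
ci_betas <- function(beta, se) {
  if (any(se < 0)) stop("se must be >= 0", call. = FALSE)
  tibble::tibble(beta_lo = pmax(0, beta - 1.96 * se),
                 beta_hi = beta + 1.96 * se)
}

.days_in_year <- function(year) {
  365L + as.integer((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0)
}

.pop_column <- c(all = "population", `0_17` = "pop_0_17",
                 `18_64` = "pop_18_64", `65plus` = "pop_65plus",
                 `30plus` = "pop_30plus")

#' Long-term wood-heater smoke mortality burden
#'
#' Annual attributable deaths per area-year from chronic WHS exposure. The
#' exposure metric is the annual mean of WHS-attributable PM2.5 taken over
#' every observed day of the year (zeros on non-WHS days), combined with
#' the annual 30+ mortality rate and 30+ population. Partial area-years are
#' computed pro-rata on the observed fraction of the year, with a warning.
#'
#' @param classified Output of [classify_days()].
#' @param areas Area table with populations.
#' @param rates Baseline rates (see [default_baseline_rates()]).
#' @param drf Dose-response table (see [default_dose_response()]).
#' @return Tibble per area x year with `outcome`, `source`, `delta_c`,
#'   `cases`, `cases_lo`, `cases_hi`.
#' @export
whs_mortality_burden <- function(classified, areas,
                                 rates = default_baseline_rates(),
                                 drf = default_dose_response()) {
  row <- drf |> filter(.data$outcome == "all_cause_mortality",
                       .data$smoke_type == "WHS",
                       .data$exposure_window == "annual")
  stopifnot(nrow(row) == 1)
  ir <- rates$rate[rates$outcome == "all_cause_mortality" &
                     rates$age_group == row$age_group]
  stopifnot(length(ir) == 1)
  ci <- ci_betas(row$beta, row$se)

  ann <- classified |>
    mutate(year = as.integer(format(.data$date, "%Y")),
           whs_attr = ifelse(.data$day_type == "WHS",
                             .data$pm25_attributable, 0)) |>
    group_by(.data$area_id, .data$year) |>
    summarise(n_days = n(), delta_c = mean(.data$whs_attr), .groups = "drop") |>
    mutate(frac_year = pmin(1, .data$n_days / .days_in_year(.data$year)))
  if (any(ann$frac_year < 1)) {
    warning(sum(ann$frac_year < 1),
            " partial area-year(s) computed pro-rata", call. = FALSE)
  }
  ann |>
    left_join(areas |> select("area_id",
                              pop = all_of(unname(.pop_column[row$age_group]))),
              by = "area_id") |>
    mutate(outcome = "all_cause_mortality", source = "WHS",
           cases = ir * .data$frac_year * .data$pop * expm1(row$beta * .data$delta_c),
           cases_lo = ir * .data$frac_year * .data$pop * expm1(ci$beta_lo * .data$delta_c),
           cases_hi = ir * .data$frac_year * .data$pop * expm1(ci$beta_hi * .data$delta_c)) |>
    select("area_id", "year", "outcome", "source", "delta_c",
           "cases", "cases_lo", "cases_hi")
}

#' Short-term (daily-exposure) burden for all outcomes
#'
#' Per polluted area-day, attributable cases for every applicable daily
#' dose-response row: LFS all-cause mortality, cardiovascular and
#' respiratory admissions (same coefficients for both sources), and asthma
#' ED visits with source-specific, age-banded coefficients. Daily baseline
#' rates are annual rates divided by the days in that calendar year.
#'
#' @inheritParams whs_mortality_burden
#' @return Tibble per area x date x outcome x age band with `source`,
#'   `cases`, `cases_lo`, `cases_hi`.
#' @export
short_term_burden <- function(classified, areas,
                              rates = default_baseline_rates(),
                              drf = default_dose_response()) {
  daily_drf <- drf |>
    filter(.data$exposure_window == "daily") |>
    mutate(smoke_type = ifelse(.data$smoke_type == "both",
                               "WHS,LFS", .data$smoke_type)) |>
    tidyr::separate_rows("smoke_type", sep = ",")
  need <- classified |>
    filter(.data$day_type %in% c("WHS", "LFS")) |>
    distinct(.data$day_type)
  missing_pairs <- setdiff(need$day_type, unique(daily_drf$smoke_type))
  if (length(missing_pairs) > 0) {
    stop("no daily dose-response rows for source(s): ",
         paste(missing_pairs, collapse = ", "), call. = FALSE)
  }

  polluted <- classified |>
    filter(.data$day_type %in% c("WHS", "LFS")) |>
    mutate(year = as.integer(format(.data$date, "%Y")))

  polluted |>
    inner_join(daily_drf, by = c(day_type = "smoke_type"),
               relationship = "many-to-many") |>
    inner_join(rates, by = c("outcome", "age_group")) |>
    mutate(pop_col = unname(.pop_column[.data$age_group])) |>
    left_join(areas |>
                select("area_id", all_of(unname(.pop_column))) |>
                tidyr::pivot_longer(-"area_id", names_to = "pop_col",
                                    values_to = "pop"),
              by = c("area_id", "pop_col"),
              relationship = "many-to-one") |>
    mutate(ir_daily = .data$rate / .days_in_year(.data$year),
           beta_lo = pmax(0, .data$beta - 1.96 * .data$se),
           beta_hi = .data$beta + 1.96 * .data$se,
           cases = .data$ir_daily * .data$pop * expm1(.data$beta * .data$pm25_attributable),
           cases_lo = .data$ir_daily * .data$pop * expm1(.data$beta_lo * .data$pm25_attributable),
           cases_hi = .data$ir_daily * .data$pop * expm1(.data$beta_hi * .data$pm25_attributable)) |>
    transmute(.data$area_id, .data$date, .data$year,
              source = .data$day_type, .data$outcome, .data$age_group,
              .data$cases, .data$cases_lo, .data$cases_hi)
}

#' Aggregate impact estimates
#'
#' Grouped sums of central estimates and confidence bounds (bound-wise CI
#' summation, a conservative approximation that preserves ordering).
#'
#' @param impacts Tibble with `cases`, `cases_lo`, `cases_hi` and grouping
#'   columns.
#' @param by Character vector of grouping columns.
#' @return Tibble of grouped totals.
#' @export
aggregate_impacts <- function(impacts, by = c("source", "outcome")) {
  impacts |>
    group_by(across(all_of(by))) |>
    summarise(cases = sum(.data$cases),
              cases_lo = sum(.data$cases_lo),
              cases_hi = sum(.data$cases_hi),
              .groups = "drop")
}

#' Full health-impact assessment over classified area-days
#'
#' Combines the long-term WHS mortality burden with the short-term burden
#' for all other outcome-source pairs.
#'
#' @inheritParams whs_mortality_burden
#' @return List with `by_day` (short-term, per area-day), `by_area_year`
#'   (WHS mortality), and `summary` (per source x outcome totals).
#' @export
compute_health_impacts <- function(classified, areas,
                                   rates = default_baseline_rates(),
                                   drf = default_dose_response()) {
  annual <- whs_mortality_burden(classified, areas, rates, drf)
  daily <- short_term_burden(classified, areas, rates, drf)
  summary <- bind_rows(
    aggregate_impacts(annual, by = c("source", "outcome")),
    aggregate_impacts(daily, by = c("source", "outcome"))
  ) |> arrange(.data$source, .data$outcome)
  list(by_day = daily, by_area_year = annual, summary = summary)
}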