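#' Cost model for health-cost valuation
#'
#' Monetary parameters for valuing attributable cases: value of statistical
#' life (VSL) for premature deaths, cost-of-illness per hospital admission
#' (either a bundled per-case total, or direct cost plus lost salary over
#' the length of stay), a per-case emergency-department cost, and inflation
#' factors that bring each source price year onto the common target year.
#' Defaults follow Australian practice: VSL of AUD$4.2 million (2014
#' prices), per-admission costs of AUD$7193 (cardiovascular) and AUD$7280
#' (respiratory) in 2016 prices, AUD$705 per ED visit (2016 prices), all
#' expressed in 2018 dollars.
#'
#' @param vsl Value of statistical life, in `vsl_year` dollars.
#' @param vsl_year Price year of `vsl`.
#' @param unit_cost_cvd,unit_cost_rsp Per-admission costs, `unit_cost_year`
#'   dollars. In bundled mode these are complete per-case costs; in
#'   component mode they are the direct health-care component.
#' @param unit_cost_ed Per-ED-visit cost, `unit_cost_year` dollars.
#' @param unit_cost_year Price year of the unit costs.
#' @param mean_los_cvd,mean_los_rsp Mean length of stay (days), used in
#'   component mode.
#' @param daily_salary Average daily salary (lost productivity per
#'   hospitalization day), used in component mode.
#' @param cost_mode `"bundled"` (default: unit costs are complete per-case
#'   totals) or `"component"` (direct cost + length of stay x salary).
#' @param inflation_factors Named numeric vector, price year to multiplier
#'   onto `target_year` dollars. Defaults are approximate Australian CPI
#'   factors; set all to 1 for price-year-naive arithmetic.
#' @param target_year Common price year for outputs.
#' @param n_woodstoves Wood heaters behind the WHS burden (for the
#'   per-woodstove-year indicator).
#' @param study_years Length of the study period in years.
#' @return List of class `cost_model`.
#' @export
cost_model <- function(vsl = 4.2e6, vsl_year = 2014,
                       unit_cost_cvd = 7193, unit_cost_rsp = 7280,
                       unit_cost_ed = 705, unit_cost_year = 2016,
                       mean_los_cvd = 6, mean_los_rsp = 5,
                       daily_salary = 240,
                       cost_mode = c("bundled", "component"),
                       inflation_factors = c("2014" = 1.07, "2016" = 1.04,
                                             "2018" = 1.0),
                       target_year = 2018,
                       n_woodstoves = 69317, study_years = 10) {
  cost_mode <- match.arg(cost_mode)
  money <- c(vsl, unit_cost_cvd, unit_cost_rsp, unit_cost_ed, daily_salary)
  if (any(!is.finite(money)) || any(money <= 0)) {
    stop("monetary parameters must be finite and > 0", call. = FALSE)
  }
  structure(list(
    vsl = vsl, vsl_year = vsl_year,
    unit_cost_cvd = unit_cost_cvd, unit_cost_rsp = unit_cost_rsp,
    unit_cost_ed = unit_cost_ed, unit_cost_year = unit_cost_year,
    mean_los_cvd = mean_los_cvd, mean_los_rsp = mean_los_rsp,
    daily_salary = daily_salary, cost_mode = cost_mode,
    inflation_factors = inflation_factors, target_year = target_year,
    n_woodstoves = n_woodstoves, study_years = study_years
  ), class = "cost_model")
}

#' Adjust an amount to the model's target price year
#'
#' @param amount Amount in `from_year` dollars.
#' @param from_year Source price year.
#' @param model A [cost_model()].
#' @return Amount in target-year dollars.
#' @export
inflate <- function(amount, from_year, model) {
  f <- model$inflation_factors[as.character(from_year)]
  if (is.na(f)) {
    stop("no inflation factor for price year ", from_year, call. = FALSE)
  }
  amount * unname(f)
}

#' Mortality cost via the value of statistical life
#'
#' @param cases Attributable deaths (vectorized).
#' @param model A [cost_model()].
#' @return Cost in target-year dollars.
#' @export
mortality_cost <- function(cases, model) {
  stopifnot(all(cases >= 0))
  cases * inflate(model$vsl, model$vsl_year, model)
}

#' Hospital-admission cost (cost of illness)
#'
#' Bundled mode multiplies cases by the per-case unit cost (which already
#' covers direct care and lost productivity); component mode adds length
#' of stay times daily salary to the direct unit cost.
#'
#' @param cases Attributable admissions (vectorized).
#' @param outcome `"cvd"` or `"rsp"`.
#' @param model A [cost_model()].
#' @return Cost in target-year dollars.
#' @export
admission_cost <- function(cases, outcome, model) {
  stopifnot(all(cases >= 0))
  per_case <- switch(outcome,
    cvd = if (model$cost_mode == "bundled") model$unit_cost_cvd
          else model$unit_cost_cvd + model$mean_los_cvd * model$daily_salary,
    rsp = if (model$cost_mode == "bundled") model$unit_cost_rsp
          else model$unit_cost_rsp + model$mean_los_rsp * model$daily_salary,
    stop("unknown admission outcome: ", outcome, call. = FALSE)
  )
  cases * inflate(per_case, model$unit_cost_year, model)
}

#' Emergency-department visit cost
#'
#' @param cases Attributable ED visits (vectorized).
#' @param model A [cost_model()].
#' @return Cost in target-year dollars.
#' @export
ed_cost <- function(cases, model) {
  stopifnot(all(cases >= 0))
  cases * inflate(model$unit_cost_ed, model$unit_cost_year, model)
}

.cost_per_outcome <- function(cases, outcome, model) {
  switch(outcome,
    all_cause_mortality = mortality_cost(cases, model),
    cvd_admission = admission_cost(cases, "cvd", model),
    rsp_admission = admission_cost(cases, "rsp", model),
    asthma_ed = ed_cost(cases, model),
    stop("unknown outcome: ", outcome, call. = FALSE)
  )
}

#' Monetize an impact summary
#'
#' Applies the outcome-appropriate valuation (VSL or cost of illness) to
#' central estimates and confidence bounds alike; monotone costing
#' preserves CI ordering.
#'
#' @param impact_summary Tibble with `source`, `outcome`, `cases`,
#'   `cases_lo`, `cases_hi` (totals over the study period).
#' @param model A [cost_model()].
#' @return Tibble adding `cost`, `cost_lo`, `cost_hi` (target-year
#'   dollars) and `cost_mode`.
#' @export
cost_impacts <- function(impact_summary, model = cost_model()) {
  impact_summary |>
    rowwise() |>
    mutate(cost = .cost_per_outcome(.data$cases, .data$outcome, model),
           cost_lo = .cost_per_outcome(.data$cases_lo, .data$outcome, model),
           cost_hi = .cost_per_outcome(.data$cases_hi, .data$outcome, model)) |>
    ungroup() |>
    mutate(cost_mode = model$cost_mode)
}

#' Policy indicators from cost totals
#'
#' Pure arithmetic shared by the pipeline and by recomputation from
#' published totals: cost per source-day, per year, and (for WHS) per
#' woodstove-year.
#'
#' @param total_cost Total cost over the study period.
#' @param n_source_days Number of days carrying the source (0 days gives a
#'   missing per-day indicator).
#' @param study_years Study length in years.
#' @param n_woodstoves Wood-heater count; `NA` to skip the indicator.
#' @return Tibble with `total_cost`, `cost_per_day`, `cost_per_year`,
#'   `cost_per_woodstove_year`.
#' @export
indicators <- function(total_cost, n_source_days, study_years,
                       n_woodstoves = NA) {
  if (study_years <= 0) stop("study_years must be > 0", call. = FALSE)
  per_year <- total_cost / study_years
  tibble::tibble(
    total_cost = total_cost,
    cost_per_day = ifelse(n_source_days > 0, total_cost / n_source_days,
                          NA_real_),
    cost_per_year = per_year,
    cost_per_woodstove_year = ifelse(is.na(n_woodstoves), NA_real_,
                                     per_year / n_woodstoves)
  )
}

#' Count source-days for per-day cost indicators
#'
#' Default (`"calendar"`): a calendar day counts once for a source if any
#' area carries that label that day. `"area_day"` counts every area-day.
#'
#' @param classified Output of [classify_days()].
#' @param counting `"calendar"` or `"area_day"`.
#' @return Tibble `source`, `n_days`.
#' @export
count_source_days <- function(classified, counting = c("calendar", "area_day")) {
  counting <- match.arg(counting)
  df <- classified |> filter(.data$day_type %in% c("WHS", "LFS"))
  if (counting == "calendar") df <- df |> distinct(.data$day_type, .data$date)
  df |> count(source = .data$day_type, name = "n_days")
}

#' Cost indicator table per source
#'
#' Combines per-source cost totals with day counts and study length into
#' the indicator schema used for reporting: total cost, cost per
#' source-day, cost per year, and cost per woodstove-year (WHS only).
#'
#' @param costs Output of [cost_impacts()].
#' @param classified Output of [classify_days()] (for day counts and study
#'   length).
#' @param model A [cost_model()]; `study_years = NULL` in `...` is derived
#'   from the data span when `derive_years` is TRUE.
#' @param counting Source-day counting rule (see [count_source_days()]).
#' @param derive_years Derive study length from the classified date span
#'   (default) instead of `model$study_years`.
#' @return Tibble, one row per source with indicator columns (central, lo,
#'   hi for the total).
#' @export
cost_indicators <- function(costs, classified, model = cost_model(),
                            counting = "calendar", derive_years = TRUE) {
  study_years <- if (derive_years) {
    as.numeric(diff(range(classified$date)) + 1) / 365.25
  } else model$study_years
  day_counts <- count_source_days(classified, counting)
  totals <- costs |>
    group_by(.data$source) |>
    summarise(cost = sum(.data$cost), cost_lo = sum(.data$cost_lo),
              cost_hi = sum(.data$cost_hi), .groups = "drop") |>
    left_join(day_counts, by = "source") |>
    mutate(n_days = tidyr::replace_na(.data$n_days, 0L))
  bind_cols(
    totals |> select("source", "cost_lo", "cost_hi", "n_days"),
    purrr::pmap_dfr(
      list(totals$cost, totals$n_days, totals$source),
      function(tc, nd, src) {
        indicators(tc, nd, study_years,
                   n_woodstoves = if (src == "WHS") model$n_woodstoves else NA)
      })
  ) |>
    relocate("total_cost", .after = "source") |>
    mutate(study_years = study_years)
}
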