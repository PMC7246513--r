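#' Reported case counts from the Tasmanian biomass-smoke assessment
#'
#' Attributable case totals (central and 95% CI bounds) by source and
#' outcome over the 2010-2019 Tasmanian study period, as published. These
#' are reference inputs for consistency checks -- e.g. recomputing the WHS
#' share of mortality and morbidity -- not outputs of this package.
#'
#' @return Tibble `source`, `outcome`, `cases`, `cases_lo`, `cases_hi`.
#' @export
reported_case_counts <- function() {
  readr::read_csv(system.file("extdata", "tasmania_reported_cases.csv",
                              package = "smokeburden"),
                  col_types = "ccddd")
}

#' Reported cost totals from the Tasmanian biomass-smoke assessment
#'
#' Published total health costs (2018 AUD) by source and outcome over the
#' ten-year Tasmanian study period, used to recompute derived indicators
#' (cost per year, per woodstove-year, source shares) as arithmetic
#' consistency checks.
#'
#' @return Tibble `source`, `outcome`, `total_cost_aud`.
#' @export
reported_cost_totals <- function() {
  readr::read_csv(system.file("extdata", "tasmania_reported_costs.csv",
                              package = "smokeburden"),
                  col_types = "ccd")
}
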