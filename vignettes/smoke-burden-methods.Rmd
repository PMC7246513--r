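---
title: "Methods: attributing and costing the health burden of biomass smoke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributing and costing the health burden of biomass smoke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

smokeburden estimates the population health burden, and its monetary
value, of fine particulate matter (PM2.5) from the two dominant biomass
smoke sources of cool-temperate regions: residential wood-heater smoke
(WHS), a chronic winter exposure, and landscape-fire smoke (LFS), a
sporadic but sometimes extreme summer exposure. This vignette describes
the model chain, the assumptions behind each step, the parameters that
matter, and what the synthetic-data validation does and does not show.

## The model chain

**Exposure surface.** Hourly monitor records are collapsed to daily means
under a validity rule: an hour is valid only when its concentration is
strictly positive, and a daily mean exists only when at least 18 valid
hours are available. Zero readings are treated as invalid instrument
hours, not as true zeros; this is strict, and days dominated by zeros
simply drop out. Daily minimum and maximum temperatures give heating
degree days at each meteorological station,

$$\mathrm{HDD} = \max\!\left(0,\; 18\,^\circ\mathrm{C} - \tfrac{t_{\min}+t_{\max}}{2}\right),$$

a proxy for residential heating demand. Daily PM2.5, HDD and both
temperatures are interpolated to each statistical-area centroid by
inverse distance weighting (IDW) over stations within 100 km,
$\hat{v} = \sum_i w_i v_i / \sum_i w_i$ with $w_i = d_i^{-p}$. The power
$p$ defaults to 2 (the conventional choice; configurable), distances are
planar kilometres, and a station closer than 1 m to the centroid returns
its value directly rather than dividing by a vanishing distance. Stations
with a missing daily mean are excluded day by day. HDD is computed at the
stations and then interpolated, not recomputed from interpolated
temperatures; the two operations do not commute through the
$\max(0,\cdot)$.

**Counterfactual and attribution.** The background ("counterfactual")
concentration of each area is the mean of its summer (November–February)
daily values after excluding likely fire days — summer days whose
concentration strictly exceeds the area's 95th percentile of all
historical daily values. A day is *unpolluted* when its concentration is
at or below the counterfactual; otherwise the attributable concentration
is

$$\Delta C = \mathrm{PM}_{2.5}^{\mathrm{daily}} - \mathrm{PM}_{2.5}^{\mathrm{counterfactual}}.$$

The percentile uses linear interpolation between order statistics
(R type 7); percentile conventions differ enough across software that
this is worth pinning down. The reference distribution for the threshold
is all historical daily values for the area (a summer-only variant is
available via `history = "summer"`), and the counterfactual is computed
once per area over the full study period.

**Source labels.** Polluted winter (May–August) days are WHS; polluted
summer days are LFS; unpolluted days carry no source. For the transition
months (March, April, September, October) a random forest trained on the
season-labeled polluted days predicts the source from nine features: area
id, year, month, day of month, daily PM2.5, daily HDD, day of week, and
daily minimum and maximum temperature. A day is wholly one source — no
within-day splits.

Two classifier defaults deserve explanation, because the obvious
configuration fails in a specific, diagnosable way. The training labels
are assigned *by season*, so the calendar features (month above all)
separate the training classes perfectly, and the transition months lie in
month-value gaps the training data never populates (between August and
November, February and May). Exact-split trees place their cut points
inside those gaps arbitrarily but deterministically — in our diagnostics,
entire months (e.g. October) were routed to the fire-smoke side of the
9.5 month boundary regardless of weather, while September, on the other
side of the same boundary, was classified almost perfectly. The defaults
counter this extrapolation artifact without touching the feature list:
`mtry = 1` (one candidate feature per split) keeps the meteorological
features on most decision paths, and randomized split points
(`splitrule = "extratrees"`) spread the calendar cut points across the
gap instead of collapsing them onto one arbitrary boundary. With 500
trees and a fixed seed, training is deterministic. An exactly 0.5
posterior (rare) is broken toward WHS when the day has positive HDD,
otherwise LFS. Out-of-sample accuracy is reported on a stratified 20%
holdout of the labeled days before refitting on all of them; note this
holdout measures winter-vs-summer separability, which is near-trivial —
the transition-month agreement measured against synthetic truth is the
informative number.

**Health impacts.** Attributable cases follow the log-linear
concentration–response model

$$\text{Cases} = IR \times Pop \times \left(e^{\beta \Delta C} - 1\right)
  \;\approx\; IR \times Pop \times \beta \Delta C ,$$

with the linearization accurate to well under 1% whenever
$\beta \Delta C < 0.01$. The packaged coefficient table
(`default_dose_response()`) couples WHO-recommended coefficients for
all-cause mortality and cardiorespiratory admissions with meta-analytic
asthma emergency-department coefficients; each row carries a standard
error, and 95% confidence bounds come from plugging
$\beta \pm 1.96\,\mathrm{SE}$ (lower bound floored at zero) through the
case equation — no Monte Carlo. Wood-heater mortality is a *chronic*
effect: its $\Delta C$ is the annual mean of WHS-attributable PM2.5 over
all days of the year (zeros on non-WHS days), applied to the 30+
population with the annual incidence rate. Every other outcome — fire
mortality included, since chronic fire-smoke relationships are not
established — uses daily exposure with a daily incidence rate equal to
the annual rate divided by the days in that calendar year. No seasonal
adjustment of baseline rates is made; because wood-smoke exposure peaks
in winter when baseline rates are likely above their annual average, this
choice underestimates rather than inflates. Partial area-years are
computed pro-rata on the observed fraction of the year, with a warning.
Confidence bounds are summed bound-wise across strata, a conservative
approximation that preserves interval ordering.

**Costs.** Deaths are valued at the value of statistical life (default
AUD$4.2 million, 2014 prices); admissions at bundled per-case
cost-of-illness figures (AUD$7193 cardiovascular, AUD$7280 respiratory,
2016 prices) that already combine direct care with lost productivity — a
component mode (`direct + length-of-stay × daily salary`) is available
when the ingredients are supplied separately; emergency-department visits
at AUD$705 per case (2016 prices). Inflation factors to the 2018 target
year are configuration inputs (defaults are approximate Australian CPI
factors; set them to 1 for price-year-naive arithmetic, as the tests do
so worked examples stay exact). Indicators divide totals by: the number
of source-days (a calendar day counts once per source if *any* area
carries the label that day; an area-day variant is selectable), the study
length in years, and — for WHS — the woodstove count. Currency arithmetic
uses doubles throughout; every amount involved is far below 2^53, so the
integer worked examples are exact.

## The synthetic world

No monitor archive ships with the package, so the generator
(`generate_world()`) builds one with known ground truth. It emulates the
statistical structure the attribution method assumes:

* a low summer background (default 1.4 µg/m³) with day-to-day mean-one
  lognormal variation (CV 0.28, giving clean-day daily SDs near 0.4
  µg/m³), plus small additive hourly noise (SD 0.35 µg/m³) floored at
  0.05 µg/m³ so all recorded hours are strictly positive;
* a winter wood-heater term (default 6.3 µg/m³ on a reference winter
  day, so typical WHS days sit near 8 µg/m³) scaled by each day's HDD and
  by an area factor, shaped within the day by a bimodal diurnal profile —
  large overnight peak, smaller early-morning peak — and lit
  stochastically on cold transition-month days;
* sporadic fire events: Poisson seasonal counts (default 1.2 per area
  per summer), geometric-ish durations of 1–16 days, lognormal daily
  magnitudes (median 12 µg/m³, sdlog 1.1) whose tail reaches hundreds of
  µg/m³; transition-month prescribed-burn events at reduced rate and
  magnitude, restricted to mild (low-HDD) days. A day carries one source:
  fires suppress the heater term;
* sinusoidal southern-hemisphere temperatures (coldest mid-July) with a
  shared synoptic anomaly, so HDD *emerges* from generated temperatures
  and the HDD operation is exercised end-to-end;
* 20 areas with populations of 3,000–25,000 on a planar 160 km domain,
  18 PM and 18 meteorological stations placed at jittered area centroids
  so most areas have a monitor within a few kilometres — the dense-network
  setting the interpolation step presumes.

The truth table records, per area-day, the injected source label and the
injected daily-mean source term ("true attributable PM2.5" — measurement
noise and background variation are deliberately not part of it). Fixed
seeds give bit-identical worlds.

What the generator does **not** emulate: real geography or station
placement, meteorological inversions as a physical process (their
*statistical* signature — cold, still, high-concentration winter nights —
is what the diurnal profile and HDD coupling stand in for), correlated
multi-area fire plumes, instrument drift, or seasonal baseline-rate
variation. Passing recovery checks on this world therefore show that the
estimator chain is internally coherent — it recovers what the generator
injected under the model's own assumptions — not that the assumptions
hold for any real airshed.

## Validation quantities and problem sizes

The acceptance script (`scripts/acceptance.R`) recomputes two groups of
quantities from scratch. The first group is published-table consistency:
relative risk increases per 10 µg/m³ implied by the packaged
dose-response coefficients, and the per-year, per-woodstove-year and
source-share indicators implied by the packaged published cost and case
totals of the Tasmanian assessment. The second group is parameter
recovery on a seeded default world: the state-wide mean counterfactual
against the configured background (their relative gap stays under 10%;
individual areas can be biased upward by a few tenths of a µg/m³ where
modest fire events slip under the 95th-percentile threshold and leak into
the summer mean — visible in `evaluate_recovery()`), the mean across
areas of the per-area mean absolute error of attributable PM2.5 (around
0.3 µg/m³), transition-month label agreement with truth (above 95% at the
defaults), and the ratio of estimated to truth-based attributable cases
(within a few percent of 1).

Problem sizes are the package's own choices: the analysis scripts and the
acceptance run use the default 20-area, 36-station, three-year world
(~22,000 area-days; roughly half a million hourly records); the test
suite uses a 6-area, two-year world for most checks. Both are large
enough for every seasonal regime to appear several times while keeping a
full pipeline run in seconds.

## Known limitations

* The counterfactual inherits upward bias from sub-threshold fire days;
  the all-history percentile threshold (rather than summer-only) makes
  this more likely when winters are polluted, which is why the
  summer-only variant is exposed.
* Attribution is binary per day; genuinely mixed days are forced to one
  source.
* CI bound-wise summation overstates interval width under independence.
* The transition classifier extrapolates calendar features by
  construction; its accuracy is only measurable on synthetic truth, and
  the sensitivity grid's "excluding predicted months" scenarios are the
  honest bracket for that uncertainty.
* Costing ignores discounting, age-adjusted VSL and morbidity beyond the
  three outcome groups.
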