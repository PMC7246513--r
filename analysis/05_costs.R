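#!/usr/bin/env Rscript
# Step 5: monetize impacts and compute policy indicators.
#
# Mortality is valued with the value of statistical life, admissions with
# bundled per-case cost-of-illness, ED visits per case; indicators are
# cost per source-day, per year, and per woodstove-year (WHS).

library(smokeburden)
suppressMessages(library(dplyr))

inp <- read_world_inputs("results/synthetic_world")
classified <- readr::read_csv("results/classified_days.csv",
                              col_types = readr::cols(area_id = "c", date = "D"))
impacts_summary <- readr::read_csv("results/impacts_summary.csv",
                                   col_types = readr::cols())

model <- cost_model(n_woodstoves = sum(inp$areas$woodstoves))
costs <- cost_impacts(impacts_summary, model)
print(costs |> select(source, outcome, cost, cost_lo, cost_hi))

ind <- cost_indicators(costs, classified, model)
print(ind)
cat(sprintf("\nWHS: %.2f M/year, %.0f per woodstove-year; LFS: %.2f M/year\n",
            ind$cost_per_year[ind$source == "WHS"] / 1e6,
            ind$cost_per_woodstove_year[ind$source == "WHS"],
            ind$cost_per_year[ind$source == "LFS"] / 1e6))

readr::write_csv(costs, "results/costs_summary.csv")
readr::write_csv(ind, "results/cost_indicators.csv")
cat("wrote results/costs_summary.csv and results/cost_indicators.csv\n")
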