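#!/usr/bin/env Rscript

# Step 4 — absenteeism costs.
#
# Standardizes each person's work payments to a truncated hourly wage
# (6.72-268.63 EUR/h), imputes missing wages by regression, expresses
# everything at the 2022 price level, converts the fitted two-year duration
# differences into annual per-employee cost components via the 7.4-hour
# working day, aggregates with survey weights (full-time employees) and
# runs the stress-reduction scenarios.

suppressPackageStartupMessages(library(elma))

cohort <- read_cohort("results/data")
episodes <- utils::read.csv("results/episodes_censored.csv",
                            stringsAsFactors = FALSE)
weights <- utils::read.csv("results/analysis_weights.csv",
                           stringsAsFactors = FALSE)
baseline <- cohort$baseline
baseline$stratum <- weights$stratum[match(baseline$follow_up_id,
                                          weights$follow_up_id)]
records <- utils::read.csv("results/transition_records.csv",
                           stringsAsFactors = FALSE)
records$weight <- weights$weight[match(records$follow_up_id,
                                       weights$follow_up_id)]

fit <- suppressWarnings(
  elma(records, baseline, n_resamples = 500, seed = 77))
wages <- person_wages(episodes, baseline)
costs <- compute_costs(fit, wages, national_workforce = 2275785)

utils::write.csv(costs$table$cells, "results/costs_cells.csv",
                 row.names = FALSE)
utils::write.csv(costs$table$totals, "results/costs_totals.csv",
                 row.names = FALSE)
writeLines(format_cost_report(costs$table), "results/costs.txt")
scen <- do.call(rbind, lapply(c(0.1, 0.5, 1.0), function(f)
  reduction_scenario(costs$person_costs, f, seed = 77)))
utils::write.csv(scen, "results/reduction_scenarios.csv", row.names = FALSE)

tt <- costs$table$totals
for (i in seq_len(nrow(tt)))
  cat(sprintf(
    "%s: %.0f EUR per exposed employee per year (sickness share %.0f%%)\n",
    c(F = "Women", M = "Men")[tt$sex[i]], tt$absenteeism_avg[i],
    tt$sickness_absence_share_pct[i]))
cat(sprintf("Wage sources: %s\n",
            paste(names(table(wages$wage_source)),
                  table(wages$wage_source), collapse = ", ")))
cat("Reduction scenarios (absenteeism):",
    sprintf("f=%.0f%% -> -%.1f%%", 100 * scen$f,
            scen$absenteeism_reduction_pct), "\n")
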