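#!/usr/bin/env Rscript
# Stage 2 — composite the satellite columns and assemble the N budget.
#
# Reads the bundle from results/bundle/, composites the daily NO2/NH3
# columns into monthly means, allocates the configured deposition totals,
# assembles the regional + national flux table and prints the budget
# summary. Writes results/flux_table.csv and results/budget_report.txt.

suppressPackageStartupMessages(library(nbudget))

bundle <- read_synth_bundle("results/bundle")

no2 <- monthly_mean(bundle$columns$no2)
nh3 <- monthly_mean(bundle$columns$nh3)
cat(sprintf("monthly composites: NO2 %d cells (%d unobserved), NH3 %d (%d)\n",
            length(no2$values), sum(is.na(no2$values)),
            length(nh3$values), sum(is.na(nh3$values))))

index <- deposition_index(no2, nh3,
                          bundle$coefficients$deposition_index_weights)
dep <- deposition_by_landuse(index, bundle$landuse,
                             bundle$coefficients$deposition_totals,
                             region_raster = bundle$counties,
                             regions = bundle$regions)

budget <- assemble_budget(bundle$regions, bundle$coefficients, dep$table)
write_flux_table(budget, "results/flux_table.csv")

rep <- budget_report(budget)
writeLines(rep$text, "results/budget_report.txt")
cat(rep$text, sep = "\n")

# check against the generator's ground truth
gt <- bundle$ground_truth
nat <- budget[budget$region_id == "national", ]
m <- merge(gt, nat, by = c("landuse", "item"), suffixes = c("_gt", "_got"))
rel <- abs(m$kgN_per_yr_got - m$kgN_per_yr_gt) / pmax(m$kgN_per_yr_gt, 1)
cat(sprintf("\nground-truth recovery: max relative error %.2e over %d fluxes\n",
            max(rel), nrow(m)))
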