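#!/usr/bin/env Rscript
# Stage 4 — validation summary.
#
# Compares the assembled budget against the generator's ground truth,
# re-checks every conservation audit from the map stage, screens the
# regional flux records for extreme values, and writes
# results/validation.csv.

suppressPackageStartupMessages(library(nbudget))

bundle <- read_synth_bundle("results/bundle")
budget <- read_flux_table("results/flux_table.csv")
audits <- read.csv("results/maps/conservation_audits.csv")

gt <- bundle$ground_truth
nat <- budget[budget$region_id == "national", ]
m <- merge(gt, nat, by = c("landuse", "item"), suffixes = c("_gt", "_got"))
m$rel_err <- abs(m$kgN_per_yr_got - m$kgN_per_yr_gt) /
  pmax(m$kgN_per_yr_gt, 1)

# QA/QC over the per-county records of each item
reg <- budget[budget$region_id != "national", ]
qa <- qaqc_screen(reg)
cat(sprintf("QA/QC: %d of %d regional records flagged as extreme\n",
            sum(qa$table$qaqc_flag), nrow(reg)))

out <- data.frame(check = c("ground-truth recovery (max rel err)",
                            "map conservation (max rel err)",
                            "QA/QC flagged records"),
                  value = c(max(m$rel_err), max(audits$rel_err),
                            sum(qa$table$qaqc_flag)))
write.csv(out, "results/validation.csv", row.names = FALSE)
print(out, row.names = FALSE)

stopifnot(max(m$rel_err) <= 1e-9, max(audits$rel_err) <= 1e-9)
cat("all validation checks passed\n")
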