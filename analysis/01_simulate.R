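#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Generates the default 15-participant cohort (12 non-OCP users, 3 OCP-user
# controls): one full menstrual cycle of daily oral thermometer readings per
# participant plus a minute-resolution overnight armband stream per night,
# with ground truth (ovulatory status, ovulation day). Writes the three CSVs
# consumed by the later steps.

library(bbtagree)

seed <- 1L
out_dir <- "results/cohort"

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, out_dir)

print(cohort)
cat("\nGround truth:\n")
print(as.data.frame(cohort$truth))
cat("\nWrote daily.csv, minutes.csv, truth.csv to", out_dir, "\n")
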