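#!/usr/bin/env Rscript
# Step 2: reduce overnight streams to daily pre-waking basal values.
#
# Reads the cohort CSVs from step 1, detects each night's waking time (the
# last on-body minute: the protocol removes the band on waking), averages the
# 10/30/60/90/120-minute pre-waking windows, and merges them with the oral
# log into the daily basal table. Reports the device-level statistics that
# the comparison study tabulates: means, SDs and recorded ranges.

library(bbtagree)

in_dir <- "results/cohort"
series <- unname(Filter(function(s) s$device == "oral",
                        read_daily_csv(file.path(in_dir, "daily.csv"))))
streams <- unname(read_minute_csv(file.path(in_dir, "minutes.csv")))

basal <- daily_basal_table(series, streams)
write.csv(basal, "results/daily_basal.csv", row.names = FALSE)

cat(sprintf("Merged %d participant-days (%d with armband data)\n",
            nrow(basal), sum(!is.na(basal$armband_60))))
cat(sprintf("Oral:        mean %.1f C (SD %.1f), range %.1f-%.1f\n",
            mean(basal$oral, na.rm = TRUE), sd(basal$oral, na.rm = TRUE),
            min(basal$oral, na.rm = TRUE), max(basal$oral, na.rm = TRUE)))
cat(sprintf("Armband 60m: mean %.1f C (SD %.1f), range %.1f-%.1f\n",
            mean(basal$armband_60, na.rm = TRUE),
            sd(basal$armband_60, na.rm = TRUE),
            min(basal$armband_60, na.rm = TRUE),
            max(basal$armband_60, na.rm = TRUE)))
cat("Wrote results/daily_basal.csv\n")
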