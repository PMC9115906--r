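#!/usr/bin/env Rscript

# Fit the battery of simple linear relationships (RT vs RR, PS, head ST,
# WC, DMI, ...) per treatment group and pooled, on group-day means, and
# the per-day Welch contrasts between arms.

suppressPackageStartupMessages(library(heatloop))

daily <- readr::read_csv("results/daily_summary.csv",
                         show_col_types = FALSE)

battery <- run_battery(daily)
readr::write_csv(battery, "results/battery.csv")

contrasts <- per_day_contrast(daily)
readr::write_csv(contrasts, "results/contrasts.csv")

rr <- battery[battery$x_name == "mean_rt" & battery$y_name == "mean_rr" &
                battery$group == "TC", ]
cat(sprintf("TC RR ~ RT slope: %.1f bpm/degC (r = %.3f, p = %.2g)\n",
            rr$slope, rr$pearson_r, rr$p_value))
cat("battery -> results/battery.csv, contrasts -> results/contrasts.csv\n")
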