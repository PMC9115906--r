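#!/usr/bin/env Rscript

# Clean the raw observation stream (RT sanitization at the 35 degC
# floor) and collapse everything to per-animal daily means joined with
# feed intake, water consumption and liveweight.

suppressPackageStartupMessages(library(heatloop))

obs <- read_observations_csv("results/cohort/observations.csv")
feed <- readr::read_csv("results/cohort/feed.csv", show_col_types = FALSE)
lw <- readr::read_csv("results/cohort/lw.csv", show_col_types = FALSE)

rt_rows <- obs$measure == "RT"
san <- sanitize_rt(obs[rt_rows, ], floor_c = 35)
cat(sprintf("RT sanitization: %d retained, %d rejected\n",
            nrow(san$retained), nrow(san$rejected)))

clean <- dplyr::bind_rows(san$retained, obs[!rt_rows, ])
daily <- aggregate_daily(clean, feed = feed, lw = lw)

climate <- read_climate_csv("results/cohort/climate.csv")
cl_daily <- dplyr::summarise(
  dplyr::group_by(climate, treatment, day),
  thi_max = max(thi), thi_min = min(thi), thi_mean = mean(thi),
  ta_max = max(ta_c), ta_min = min(ta_c), .groups = "drop")
daily <- dplyr::left_join(daily, cl_daily, by = c("treatment", "day"))
readr::write_csv(daily, "results/daily_summary.csv")
cat(sprintf("daily summary: %d animal-days -> results/daily_summary.csv\n",
            nrow(daily)))
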