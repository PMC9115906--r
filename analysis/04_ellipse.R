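#!/usr/bin/env Rscript

# Fit the elliptical hysteresis loop in the (RT, DMI) plane for each
# treatment arm from group-day means, and report geometry, traversal
# direction and fit quality.

suppressPackageStartupMessages(library(heatloop))

daily <- readr::read_csv("results/daily_summary.csv",
                         show_col_types = FALSE)
gm <- dplyr::summarise(
  dplyr::group_by(daily, treatment, day),
  rt = mean(mean_rt, na.rm = TRUE),
  dmi = mean(dmi, na.rm = TRUE), .groups = "drop")

for (g in unique(gm$treatment)) {
  sub <- gm[gm$treatment == g, ]
  sub <- sub[order(sub$day), ]
  loop <- fit_ellipse_loop(tibble::tibble(x = sub$rt, y = sub$dmi))
  ellipse_to_json(loop, sprintf("results/ellipse_%s.json", g))
  geo <- loop$geometry
  cat(sprintf(
    "%s: center (%.2f degC, %.2f kg), %s, R2(response) = %.3f\n",
    g, geo$center[1], geo$center[2], geo$direction,
    loop$r2$r2_response))
}
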