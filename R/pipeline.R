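#' End-to-end analysis pipeline
#'
#' Runs the full chain — climate summaries, preprocessing to daily means,
#' the linear-relationship battery, per-day group contrasts, and per-group
#' (RT, DMI) ellipse fits — on either a simulated cohort (`simulate =
#' TRUE`) or supplied file paths, and writes a report bundle to `out_dir`:
#' `daily_summary.csv`, `battery.csv`, `contrasts.csv`,
#' `ellipse_<group>.json`, `report.md` and a `manifest.json` of completed
#' stages. Rerunning with the same seed and inputs reproduces the bundle
#' byte-for-byte.
#'
#' @param out_dir Output directory.
#' @param simulate Logical; generate the cohort with [simulate_cohort()].
#' @param seed Seed for simulate mode.
#' @param config `sim_config()` overrides (simulate mode) — a `sim_config`
#'   object; its seed is replaced by `seed`.
#' @param paths Named list with `observations`, `feed`, `lw` (file mode);
#'   optionally `climate`.
#' @param sanitize_floor_c RT removal threshold, degrees C.
#' @param drop_day1_wc Passed to [run_battery()].
#' @return Invisible list with `daily`, `battery`, `contrasts`, `ellipses`,
#'   `manifest`.
#' @export
run_pipeline <- function(out_dir, simulate = TRUE, seed = 1L,
                         config = NULL, paths = NULL,
                         sanitize_floor_c = 35, drop_day1_wc = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = character(0))
  save_manifest <- function() {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
               file.path(out_dir, "manifest.json"))
  }

  # ---- stage: inputs ---------------------------------------------------
  if (simulate) {
    cfg <- if (is.null(config)) sim_config(seed = seed) else {
      config$seed <- as.integer(seed); validate_sim_config(config)
    }
    sim <- simulate_cohort(cfg)
    obs <- sim$observations; feed <- sim$feed; lw <- sim$lw
    climate <- sim$climate
  } else {
    if (is.null(paths)) {
      abort("file mode needs `paths`", class = "heatloop_validation")
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) {
        abort(sprintf("input file not found: %s", p),
              class = "heatloop_validation")
      }
    }
    obs <- read_observations_csv(paths$observations)
    if (nrow(obs) == 0L) {
      abort(sprintf("observations file is empty: %s", paths$observations),
            class = "heatloop_validation")
    }
    feed <- readr::read_csv(paths$feed, show_col_types = FALSE)
    lw <- readr::read_csv(paths$lw, show_col_types = FALSE)
    climate <- if (!is.null(paths$climate)) {
      cl <- readr::read_csv(paths$climate, show_col_types = FALSE)
      cl$ta <- cl$ta_c; cl$rh <- cl$rh_pct; cl
    } else NULL
  }
  manifest$stages <- c(manifest$stages, "inputs"); save_manifest()

  # ---- stage: preprocess ----------------------------------------------
  rt_rows <- obs$measure == "RT"
  san <- sanitize_rt(obs[rt_rows, ], floor_c = sanitize_floor_c)
  obs_clean <- dplyr::bind_rows(san$retained, obs[!rt_rows, ])
  daily <- aggregate_daily(obs_clean, feed = feed, lw = lw)

  if (!is.null(climate)) {
    climate$thi <- compute_thi(climate$ta, climate$rh)
    cl_daily <- dplyr::summarise(
      dplyr::group_by(climate, .data$treatment, .data$day),
      thi_max = max(.data$thi), thi_min = min(.data$thi),
      thi_mean = mean(.data$thi),
      ta_max = max(.data$ta), ta_min = min(.data$ta), .groups = "drop")
    daily <- dplyr::left_join(daily, cl_daily, by = c("treatment", "day"))
  }
  readr::write_csv(daily, file.path(out_dir, "daily_summary.csv"))
  if (nrow(san$rejected) > 0L) {
    rej <- san$rejected
    rej$timestamp <- format(rej$timestamp, "%Y-%m-%dT%H:%M:%SZ")
    writeLines(vapply(seq_len(nrow(rej)), function(i) {
      jsonlite::toJSON(as.list(rej[i, ]), auto_unbox = TRUE, digits = NA)
    }, character(1)), file.path(out_dir, "rejections.ndjson"))
  }
  manifest$stages <- c(manifest$stages, "preprocess"); save_manifest()

  # ---- stage: linear battery + contrasts ------------------------------
  battery <- run_battery(daily, drop_day1_wc = drop_day1_wc)
  readr::write_csv(battery, file.path(out_dir, "battery.csv"))
  contrasts <- per_day_contrast(daily)
  readr::write_csv(contrasts, file.path(out_dir, "contrasts.csv"))
  manifest$stages <- c(manifest$stages, "battery"); save_manifest()

  # ---- stage: ellipses (RT x DMI per group) ---------------------------
  grp_daily <- dplyr::summarise(
    dplyr::group_by(daily, .data$treatment, .data$day),
    rt = mean(.data$mean_rt, na.rm = TRUE),
    dmi = mean(.data$dmi, na.rm = TRUE), .groups = "drop")
  ellipses <- list()
  for (g in unique(grp_daily$treatment)) {
    sub <- grp_daily[grp_daily$treatment == g, ]
    sub <- sub[order(sub$day), ]
    pts <- tibble::tibble(x = sub$rt, y = sub$dmi)
    pts <- pts[stats::complete.cases(pts), ]
    loop <- tryCatch(fit_ellipse_loop(pts), error = function(e) e)
    ellipses[[g]] <- loop
    if (!inherits(loop, "error")) {
      ellipse_to_json(loop, file.path(out_dir,
                                      sprintf("ellipse_%s.json", g)))
    }
  }
  manifest$stages <- c(manifest$stages, "ellipse"); save_manifest()

  # ---- stage: report ---------------------------------------------------
  writeLines(render_report(daily, battery, contrasts, ellipses),
             file.path(out_dir, "report.md"))
  manifest$stages <- c(manifest$stages, "report"); save_manifest()

  invisible(list(daily = daily, battery = battery, contrasts = contrasts,
                 ellipses = ellipses, manifest = manifest))
}

render_report <- function(daily, battery, contrasts, ellipses) {
  lines <- c("# Thermal challenge and recovery report", "")

  lines <- c(lines, "## Per-period group means (mean ± SEM)", "")
  meas <- intersect(c("mean_rt", "mean_rr", "mean_ps", "mean_st_head",
                      "dmi", "wc"), names(daily))
  per <- dplyr::summarise(
    dplyr::group_by(daily, .data$treatment, .data$period),
    dplyr::across(dplyr::all_of(meas),
                  list(m = ~mean(.x, na.rm = TRUE),
                       sem = ~stats::sd(.x, na.rm = TRUE) /
                         sqrt(sum(is.finite(.x))))),
    .groups = "drop")
  hdr <- c("group", "period", meas)
  lines <- c(lines, paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"),
                    "|"))
  for (i in seq_len(nrow(per))) {
    cells <- vapply(meas, function(m) {
      sprintf("%.2f ± %.2f", per[[paste0(m, "_m")]][i],
              per[[paste0(m, "_sem")]][i])
    }, character(1))
    lines <- c(lines, paste0("| ", per$treatment[i], " | ", per$period[i],
                             " | ", paste(cells, collapse = " | "), " |"))
  }

  lines <- c(lines, "", "## Linear relationship battery", "")
  lines <- c(lines, "| y ~ x | group | slope | r | p | n | label |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(battery))) {
    b <- battery[i, ]
    lines <- c(lines, sprintf(
      "| %s ~ %s | %s | %.4g | %.3f | %.4g | %d | %s |",
      b$y_name, b$x_name, b$group, b$slope, b$pearson_r, b$p_value, b$n,
      b$label))
  }

  lines <- c(lines, "", "## RT x DMI ellipses", "")
  for (g in names(ellipses)) {
    e <- ellipses[[g]]
    if (inherits(e, "error")) {
      lines <- c(lines, sprintf("* %s: fit failed (%s)", g,
                                conditionMessage(e)))
    } else {
      gm <- e$geometry
      lines <- c(lines, sprintf(
        paste0("* %s: center (%.2f degC, %.2f kg), semi-axes %.3f/%.3f, ",
               "direction %s, R2(response) %.3f, R2(Sampson) %.3f; ",
               "max DMI %.2f kg at RT %.2f degC; min DMI %.2f kg at RT ",
               "%.2f degC"),
        g, gm$center[1], gm$center[2], gm$semi_major, gm$semi_minor,
        gm$direction, e$r2$r2_response, e$r2$r2_sampson,
        gm$y_max_point[["y"]], gm$y_max_point[["x"]],
        gm$y_min_point[["y"]], gm$y_min_point[["x"]]))
    }
  }
  lines
}
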