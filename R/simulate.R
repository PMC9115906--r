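#' Configuration for the synthetic paired-cohort generator
#'
#' Assembles (and validates) the full parameter set of the virtual
#' thermally-challenged / feed-restricted-thermoneutral (TC/FRTN) trial.
#' Defaults emulate the study conditions of an 18-day, 18-pair
#' climate-controlled-room experiment: thermoneutral THI band 68-71 in
#' Pre-Challenge (days 1-4) and Recovery (days 12-18), diurnal Challenge
#' cycling THI 73-84 (days 5-11), FRTN held at THI 67.2; a fast first-order
#' rumen-temperature (RT) response above a THI threshold of 74 and a slow
#' first-order dry-matter-intake (DMI) suppression above an RT threshold,
#' whose differing time constants close a clockwise hysteresis loop in the
#' (RT, DMI) plane; and linear-in-RT responses for respiration rate (46
#' bpm/degree C), panting score (0.63/degree C), head surface temperature
#' (4.3 degrees C/degree C) and water consumption (10.5 L/degree C).
#'
#' @param n_pairs Number of TC/FRTN pairs.
#' @param n_days Trial length in days (periods: <=4, 5-11, >=12).
#' @param seed Integer seed; the generator is bit-reproducible given
#'   (config, seed).
#' @param ... Named overrides of any default component (partial lists are
#'   merged), e.g. `rt = list(thi_sensitivity = 0.25)`.
#' @return Object of class `sim_config` (named list).
#' @export
sim_config <- function(n_pairs = 18L, n_days = 18L, seed = 1L, ...) {
  cfg <- list(
    n_pairs = as.integer(n_pairs),
    n_days = as.integer(n_days),
    seed = as.integer(seed),
    challenge_days = 5:11,
    thi = list(
      neutral_min = 68, neutral_max = 71,     # TC Pre-Challenge/Recovery
      challenge_min = 73, challenge_max = 84, # TC Challenge diurnal band
      rh_neutral = 70, rh_challenge_min = 45, rh_challenge_max = 60,
      frtn_ta = 20.34, frtn_rh = 71.51,       # FRTN thermoneutral hold
      frtn_ta_sd = 0.2, frtn_rh_sd = 1.5),
    rt = list(
      baseline = 39.70,          # degrees C, thermoneutral daily mean
      thi_threshold = 74,        # THI above which RT is driven up
      thi_sensitivity = 0.25,    # degrees C per THI unit of excess
      tau_h = 3,                 # RT relaxation time constant, hours
      feed_coef = 0.08,          # degrees C per kg DMI deviation
      animal_sd = 0.10,          # between-animal baseline SD, degrees C
      bolus_sd = 0.05),          # bolus reading noise, degrees C
    dmi = list(
      baseline = 11.2,           # kg DM/steer/d incl. chaff
      rt_threshold = 39.8,       # degrees C above which intake is suppressed
      suppression = 4.5,         # kg DM per degree C of RT excess
      tau_d = 2.5,               # DMI relaxation time constant, days
      animal_sd = 0.5,           # between-animal baseline SD, kg
      intake_sd = 0.15),         # daily intake noise, kg
    recovery = list(             # adapted state from day 12
      enabled = TRUE, dmi_frac = 0.88, rt_shift = -0.23),
    frtn_bump = list(            # transient stress hyperthermia, FRTN
      enabled = FALSE, days = 3:6, magnitude = 0.2),
    responses = list(            # linear-in-RT observer measures
      RR = list(slope = 46, ref_rt = 39.7, ref_value = 78, sd = 6,
                lo = 5, hi = 200),
      PS = list(slope = 0.63, ref_rt = 39.7, ref_value = 1.3, sd = 0.15,
                lo = 0, hi = 4.5),
      ST_head = list(slope = 4.3, ref_rt = 39.7, ref_value = 24.5, sd = 1,
                     lo = 10, hi = 45),
      ST_shoulder = list(slope = 2.2, ref_rt = 39.7, ref_value = 29,
                         sd = 1, lo = 10, hi = 45),
      ST_rump = list(slope = 2.0, ref_rt = 39.7, ref_value = 28, sd = 1,
                     lo = 10, hi = 45),
      ST_leg = list(slope = 1.6, ref_rt = 39.7, ref_value = 26, sd = 1,
                    lo = 10, hi = 45)),
    wc = list(slope = 10.5, ref_rt = 39.7, ref_value = 42, sd = 4,
              min_l = 5),       # daily water consumption model, litres
    lw = list(entry_mean = 520, pair_sd = 24, within_pair_sd = 8,
              gain_per_kg = 1.2, maintenance_dmi = 9.5,
              weigh_days = c(1, 2, 5, 7, 9, 10, 12, 14, 16, 18)),
    feed = list(dm_fraction = 0.897, chaff_dm = 1.08, uplift = 0.20,
                max_daily_drop = 2.5),
    schedule = list(bolus_interval_min = 10, obs_hours = seq(6, 18, 2),
                    obs_hours_24h = seq(0, 22, 2)),
    day1_date = as.Date("2014-07-28"))

  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_pairs < 1L || n_days < 1L)
      abort("n_pairs and n_days must be positive",
            class = "heatloop_validation")
    if (rt$tau_h <= 0 || dmi$tau_d <= 0)
      abort("time constants must be positive",
            class = "heatloop_validation")
    if (dmi$tau_d <= rt$tau_h / 24)
      abort("tau_DMI (days) must exceed tau_RT (hours)/24 for a closed loop",
            class = "heatloop_validation")
    sds <- c(rt$animal_sd, rt$bolus_sd, dmi$animal_sd, dmi$intake_sd,
             wc$sd, vapply(responses, function(r) r$sd, numeric(1)))
    if (any(sds < 0))
      abort("noise standard deviations must be non-negative",
            class = "heatloop_validation")
  })
  cfg
}

# TA achieving a target THI at a given RH (inverse of compute_thi in TA)
ta_for_thi <- function(thi, rh) {
  (thi - 46.3 + 14.3 * rh / 100) / (0.8 + rh / 100)
}

# Hourly TC climate for one day from a THI band via the diurnal program
tc_day_climate <- function(cfg, challenge) {
  if (challenge) {
    rh_lo <- cfg$thi$rh_challenge_min; rh_hi <- cfg$thi$rh_challenge_max
    ta_lo <- ta_for_thi(cfg$thi$challenge_min, rh_lo)
    ta_hi <- ta_for_thi(cfg$thi$challenge_max, rh_hi)
  } else {
    rh_lo <- cfg$thi$rh_neutral; rh_hi <- cfg$thi$rh_neutral
    ta_lo <- ta_for_thi(cfg$thi$neutral_min, rh_lo)
    ta_hi <- ta_for_thi(cfg$thi$neutral_max, rh_hi)
  }
  build_diurnal_program(c(ta_lo, rh_lo), c(ta_hi, rh_hi))
}

#' Simulate a paired TC/FRTN thermal-challenge cohort
#'
#' Generates the full record set of a virtual trial under `config`:
#' hourly climate for both arms, latent hourly rumen temperature via
#' first-order relaxation toward a THI- and feed-driven equilibrium, daily
#' dry-matter intake via a slower first-order relaxation with pair-offering
#' (and gradual step-down) feeding, linear-in-RT observer measures with
#' Gaussian noise, cumulative water-meter readings, and live weight
#' integrated from intake. Records are emitted on the field schedule:
#' bolus RT every `bolus_interval_min` minutes, observer measures 2-hourly
#' 0600-1800 (around the clock during Challenge).
#'
#' @param config A [sim_config()].
#' @return List with tibbles `observations` (tidy long), `feed`, `lw`,
#'   `climate` (hourly per arm), and `ground_truth` (per-animal parameter
#'   draws, per-day latent daily means, generating slopes, config echo).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)

  n_pairs <- cfg$n_pairs; n_days <- cfg$n_days
  n_animals <- 2L * n_pairs
  treatment <- rep(c("TC", "FRTN"), each = n_pairs)
  pair_id <- sprintf("P%02d", rep(seq_len(n_pairs), 2L))
  animal_id <- sprintf("%s_%02d", treatment, rep(seq_len(n_pairs), 2L))
  cohort <- rep(((seq_len(n_pairs) - 1L) %/% 6L) + 1L, 2L)
  is_tc <- treatment == "TC"

  # ---- climate: hourly THI by day for each arm -------------------------
  tc_climate <- dplyr::bind_rows(lapply(seq_len(n_days), function(d) {
    prog <- tc_day_climate(cfg, d %in% cfg$challenge_days)
    tibble::tibble(day = d, hour = prog$hour, ta = prog$ta, rh = prog$rh)
  }))
  nh <- nrow(tc_climate)
  frtn_ta <- cfg$thi$frtn_ta + stats::rnorm(nh, 0, cfg$thi$frtn_ta_sd)
  frtn_rh <- pmin(100, pmax(0, cfg$thi$frtn_rh +
                              stats::rnorm(nh, 0, cfg$thi$frtn_rh_sd)))
  climate <- dplyr::bind_rows(
    dplyr::mutate(tc_climate, treatment = "TC"),
    tibble::tibble(day = tc_climate$day, hour = tc_climate$hour,
                   ta = frtn_ta, rh = frtn_rh, treatment = "FRTN"))
  climate$thi <- compute_thi(climate$ta, climate$rh)
  climate$timestamp <- as.POSIXct(cfg$day1_date, tz = "UTC") +
    ((climate$day - 1) * 24 + climate$hour) * 3600

  thi_hourly <- matrix(0, nrow = n_animals, ncol = n_days * 24L)
  thi_tc <- climate$thi[climate$treatment == "TC"]
  thi_fr <- climate$thi[climate$treatment == "FRTN"]
  thi_hourly[is_tc, ] <- matrix(thi_tc, nrow = sum(is_tc),
                                ncol = n_days * 24L, byrow = TRUE)
  thi_hourly[!is_tc, ] <- matrix(thi_fr, nrow = sum(!is_tc),
                                 ncol = n_days * 24L, byrow = TRUE)

  # ---- animal-level parameter draws ------------------------------------
  rt_base <- cfg$rt$baseline + stats::rnorm(n_animals, 0, cfg$rt$animal_sd)
  dmi_base <- cfg$dmi$baseline +
    rep(stats::rnorm(n_pairs, 0, cfg$dmi$animal_sd), 2L)  # pair-matched
  pair_lw <- stats::rnorm(n_pairs, cfg$lw$entry_mean, cfg$lw$pair_sd)
  lw_now <- rep(pair_lw, 2L) +
    stats::rnorm(n_animals, 0, cfg$lw$within_pair_sd)

  grain_base <- dmi_base - cfg$feed$chaff_dm

  # ---- day-by-day dynamics --------------------------------------------
  rt_now <- rt_base                       # hourly latent RT state
  dmi_des <- grain_base                   # desired grain DM, slow state
  frtn_offer_prev <- rep(NA_real_, n_pairs)
  rt_hourly <- matrix(NA_real_, n_animals, n_days * 24L)
  rt_daily <- dmi_daily <- wc_daily <- matrix(NA_real_, n_animals, n_days)
  lw_daily <- matrix(NA_real_, n_animals, n_days)
  feed_rows <- vector("list", n_days)
  prev_rt_mean <- rt_base                 # driver for day-1 intake

  for (d in seq_len(n_days)) {
    adapted <- cfg$recovery$enabled && d >= 12L
    rt_base_eff <- rt_base + if (adapted) cfg$recovery$rt_shift else 0
    if (cfg$frtn_bump$enabled && d %in% cfg$frtn_bump$days) {
      rt_base_eff[!is_tc] <- rt_base_eff[!is_tc] + cfg$frtn_bump$magnitude
    }
    grain_eff <- (dmi_base * if (adapted) cfg$recovery$dmi_frac else 1) -
      cfg$feed$chaff_dm

    # intake decisions at 0700 feeding
    if (d > 1L) {
      dmi_eq <- grain_eff - cfg$dmi$suppression *
        pmax(0, prev_rt_mean - cfg$dmi$rt_threshold)
      dmi_des <- dmi_des + (dmi_eq - dmi_des) / cfg$dmi$tau_d
      tc_offer <- pair_offer(dmi_daily[is_tc, d - 1L] - cfg$feed$chaff_dm,
                             cfg$feed$uplift)
    } else {
      dmi_des <- grain_eff
      tc_offer <- pair_offer(grain_base[is_tc], cfg$feed$uplift)
    }
    frtn_offer <- if (d == 1L) tc_offer else
      step_down_offer(frtn_offer_prev, tc_offer, cfg$feed$max_daily_drop)
    frtn_offer_prev <- frtn_offer

    offer <- numeric(n_animals)
    offer[is_tc] <- tc_offer
    offer[!is_tc] <- frtn_offer
    want <- pmax(0, dmi_des + stats::rnorm(n_animals, 0, cfg$dmi$intake_sd))
    grain_intake <- pmin(offer, want)
    dmi_daily[, d] <- grain_intake + cfg$feed$chaff_dm

    feed_rows[[d]] <- tibble::tibble(
      animal_id = animal_id, day = d,
      offered_asfed_kg = offer / cfg$feed$dm_fraction,
      refusals_asfed_kg = (offer - grain_intake) / cfg$feed$dm_fraction,
      dm_fraction = cfg$feed$dm_fraction)

    # hourly RT relaxation across the day
    feed_term <- cfg$rt$feed_coef * (dmi_daily[, d] - dmi_base)
    for (h in 1:24) {
      col <- (d - 1L) * 24L + h
      rt_eq <- rt_base_eff + cfg$rt$thi_sensitivity *
        pmax(0, thi_hourly[, col] - cfg$rt$thi_threshold) + feed_term
      rt_now <- rt_now + (rt_eq - rt_now) / cfg$rt$tau_h
      rt_hourly[, col] <- rt_now
    }
    rt_daily[, d] <- rowMeans(rt_hourly[, (d - 1L) * 24L + 1:24,
                                        drop = FALSE])
    prev_rt_mean <- rt_daily[, d]

    wc_daily[, d] <- pmax(cfg$wc$min_l,
      cfg$wc$ref_value + cfg$wc$slope * (rt_daily[, d] - cfg$wc$ref_rt) +
        stats::rnorm(n_animals, 0, cfg$wc$sd))

    lw_daily[, d] <- lw_now
    lw_now <- lw_now + cfg$lw$gain_per_kg *
      (dmi_daily[, d] - cfg$lw$maintenance_dmi)
  }

  # ---- record emission -------------------------------------------------
  day0 <- as.POSIXct(cfg$day1_date, tz = "UTC")
  meta <- tibble::tibble(animal_id = animal_id, treatment = treatment,
                         cohort = cohort, pair_id = pair_id)

  # bolus RT: every bolus_interval_min minutes, linear within the hour
  step_h <- cfg$schedule$bolus_interval_min / 60
  tt <- seq(step_h, n_days * 24, by = step_h)       # hours since day-1 00:00
  rt_grid <- t(apply(rt_hourly, 1L, function(r) {
    stats::approx(seq_len(n_days * 24L), r, xout = tt, rule = 2)$y
  }))
  n_t <- length(tt)
  bolus <- tibble::tibble(
    animal_id = rep(animal_id, each = n_t),
    day = rep(ceiling(tt / 24), n_animals),
    timestamp = day0 + rep(tt, n_animals) * 3600 - 1,
    measure = "RT",
    value = as.vector(t(rt_grid)) +
      stats::rnorm(n_animals * n_t, 0, cfg$rt$bolus_sd))

  # observer measures at scheduled hours
  # cumulative meter baseline accumulated in plain double arithmetic so a
  # day's opening reading equals the previous close bitwise (cumsum() uses
  # extended precision internally and would break meter monotonicity)
  wc_cum <- wc_daily
  for (d in seq_len(n_days)[-1L]) {
    wc_cum[, d] <- wc_cum[, d - 1L] + wc_daily[, d]
  }
  obs_list <- lapply(seq_len(n_days), function(d) {
    hrs <- if (d %in% cfg$challenge_days) cfg$schedule$obs_hours_24h else
      cfg$schedule$obs_hours
    rt_at <- rt_hourly[, (d - 1L) * 24L + hrs + 1L, drop = FALSE]
    per_measure <- lapply(names(cfg$responses), function(m) {
      p <- cfg$responses[[m]]
      v <- p$ref_value + p$slope * (rt_at - p$ref_rt) +
        stats::rnorm(length(rt_at), 0, p$sd)
      tibble::tibble(
        animal_id = rep(animal_id, times = length(hrs)),
        day = d,
        timestamp = day0 + ((d - 1) * 24 + rep(hrs, each = n_animals)) *
          3600,
        measure = m,
        value = pmin(p$hi, pmax(p$lo, as.vector(v))))
    })
    # cumulative water meter: day's WC spread linearly over the obs window
    base_d <- if (d == 1L) rep(0, n_animals) else wc_cum[, d - 1L]
    frac <- (hrs - hrs[1]) / (hrs[length(hrs)] - hrs[1])
    meter <- tibble::tibble(
      animal_id = rep(animal_id, times = length(hrs)),
      day = d,
      timestamp = day0 + ((d - 1) * 24 + rep(hrs, each = n_animals)) *
        3600,
      measure = "WC_meter",
      value = rep(base_d, times = length(hrs)) +
        rep(wc_daily[, d], times = length(hrs)) *
        rep(frac, each = n_animals))
    dplyr::bind_rows(c(per_measure, list(meter)))
  })

  observations <- dplyr::bind_rows(c(list(bolus), obs_list))
  observations <- dplyr::left_join(observations, meta, by = "animal_id")
  observations <- observations[, c("animal_id", "treatment", "cohort",
                                   "pair_id", "day", "timestamp",
                                   "measure", "value")]
  observations <- dplyr::arrange(observations, .data$animal_id,
                                 .data$timestamp, .data$measure)

  feed <- dplyr::bind_rows(feed_rows)
  lw <- tibble::tibble(
    animal_id = rep(animal_id, times = length(cfg$lw$weigh_days)),
    day = rep(cfg$lw$weigh_days, each = n_animals),
    lw_kg = as.vector(lw_daily[, cfg$lw$weigh_days]))
  lw <- lw[lw$day <= n_days, ]

  ground_truth <- list(
    config = cfg,
    animals = dplyr::bind_cols(meta, tibble::tibble(
      rt_baseline = rt_base, dmi_baseline = dmi_base,
      lw_entry = lw_daily[, 1])),
    latent_daily = tibble::tibble(
      animal_id = rep(animal_id, times = n_days),
      day = rep(seq_len(n_days), each = n_animals),
      rt_mean = as.vector(rt_daily),
      dmi = as.vector(dmi_daily),
      wc = as.vector(wc_daily),
      lw = as.vector(lw_daily)),
    generating_slopes = c(
      vapply(cfg$responses, function(p) p$slope, numeric(1)),
      WC = cfg$wc$slope))

  list(observations = observations, feed = feed, lw = lw,
       climate = climate[, c("treatment", "day", "hour", "timestamp",
                             "ta", "rh", "thi")],
       ground_truth = ground_truth)
}

#' Sample ordered points from a known ellipse
#'
#' Ground-truth mode for the ellipse engine's recovery tests: points at
#' equal parametric angles on a specified ellipse, with isotropic Gaussian
#' noise; the ordering of the angles encodes the traversal direction.
#'
#' @param center Length-2 numeric (x0, y0).
#' @param semi_major,semi_minor Semi-axis lengths (> 0).
#' @param rotation Rotation of the major axis, radians.
#' @param n Number of points (>= 6).
#' @param noise_sd Isotropic Gaussian noise SD, data units.
#' @param seed Optional integer seed.
#' @param direction `"counterclockwise"` (default) or `"clockwise"`.
#' @param start_angle Parametric angle of the first point, radians.
#' @return Tibble `x`, `y` in traversal order.
#' @export
sample_ellipse <- function(center, semi_major, semi_minor, rotation = 0,
                           n = 18L, noise_sd = 0, seed = NULL,
                           direction = c("counterclockwise", "clockwise"),
                           start_angle = 0) {
  direction <- match.arg(direction)
  stopifnot(n >= 6L, semi_major > 0, semi_minor > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- start_angle + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  if (direction == "clockwise") t <- -t
  px <- semi_major * cos(t); py <- semi_minor * sin(t)
  x <- center[1] + px * cos(rotation) - py * sin(rotation)
  y <- center[2] + px * sin(rotation) + py * cos(rotation)
  if (noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, noise_sd)
    y <- y + stats::rnorm(n, 0, noise_sd)
  }
  tibble::tibble(x = x, y = y)
}

#' Write a simulated cohort to CSV files
#'
#' Emits the exact CSV dialects consumed by the preprocessing readers,
#' plus the ground truth as JSON.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    observations = file.path(dir, "observations.csv"),
    feed = file.path(dir, "feed.csv"),
    lw = file.path(dir, "lw.csv"),
    climate = file.path(dir, "climate.csv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  obs <- sim$observations
  obs$timestamp <- format(obs$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  readr::write_csv(obs, paths["observations"])
  readr::write_csv(sim$feed, paths["feed"])
  readr::write_csv(sim$lw, paths["lw"])
  cl <- sim$climate
  cl <- tibble::tibble(timestamp = format(cl$timestamp,
                                          "%Y-%m-%dT%H:%M:%SZ"),
                       treatment = cl$treatment, day = cl$day,
                       ta_c = cl$ta, rh_pct = cl$rh)
  readr::write_csv(cl, paths["climate"])
  gt <- sim$ground_truth
  gt$config <- unclass(gt$config)
  # named atomic vectors serialize as bare arrays; keep the names
  gt$generating_slopes <- as.list(gt$generating_slopes)
  gt$config$day1_date <- as.character(gt$config$day1_date)
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"),
             paths["ground_truth"])
  invisible(paths)
}
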