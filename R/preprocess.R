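#' Respiration rate from breath timing
#'
#' Field observers record the time taken for an animal to take 10 breaths
#' (flank movement); this converts that duration to breaths per minute.
#'
#' @param seconds_for_10_breaths Duration in seconds, > 0. Vectorized.
#' @return Respiration rate, breaths per minute (`600 / seconds`).
#' @examples
#' rr_from_breath_timing(6)  # 100 bpm
#' @export
rr_from_breath_timing <- function(seconds_for_10_breaths) {
  stopifnot(is.numeric(seconds_for_10_breaths))
  if (any(!is.finite(seconds_for_10_breaths) | seconds_for_10_breaths <= 0)) {
    stop("breath timing must be a positive duration in seconds",
         call. = FALSE)
  }
  600 / seconds_for_10_breaths
}

#' Sanitize rumen-temperature records
#'
#' Applies the standard bolus-telemetry cleaning rule: readings at or below
#' `floor_c` (default 35 degrees C, well under the physiological range and
#' symptomatic of large water-drinking events or transmission faults) are
#' removed. Optionally (off by default) readings within `wc_window_min`
#' minutes after a water-consumption event of at least `wc_threshold_l`
#' litres are also masked. Every removal is logged with its reason.
#'
#' @param rt Tibble/data frame with at least `timestamp` (POSIXct) and
#'   `value` (degrees C); an `animal_id` column, if present, scopes the
#'   water-event masking per animal.
#' @param floor_c Removal threshold, degrees C; values `<= floor_c` drop.
#' @param mask_wc_events Logical; mask post-drinking readings.
#' @param wc_events Tibble with `animal_id`, `timestamp`, `litres` (required
#'   when `mask_wc_events` is TRUE).
#' @param wc_window_min Masking window after a qualifying event, minutes.
#' @param wc_threshold_l Event size that triggers masking, litres.
#' @return List with `retained` (rows kept, original order) and `rejected`
#'   (dropped rows plus a `reason` column).
#' @export
sanitize_rt <- function(rt, floor_c = 35, mask_wc_events = FALSE,
                        wc_events = NULL, wc_window_min = 60,
                        wc_threshold_l = 8) {
  stopifnot(is.data.frame(rt), "value" %in% names(rt))
  rt <- tibble::as_tibble(rt)
  reason <- rep(NA_character_, nrow(rt))
  low <- !is.na(rt$value) & rt$value <= floor_c
  reason[low] <- sprintf("rt_le_%g_c", floor_c)

  if (mask_wc_events && nrow(rt) > 0L) {
    if (is.null(wc_events)) {
      stop("`wc_events` is required when `mask_wc_events = TRUE`",
           call. = FALSE)
    }
    ev <- wc_events[wc_events$litres >= wc_threshold_l, , drop = FALSE]
    if (nrow(ev) > 0L) {
      has_id <- "animal_id" %in% names(rt) && "animal_id" %in% names(ev)
      for (i in seq_len(nrow(ev))) {
        inwin <- rt$timestamp >= ev$timestamp[i] &
          rt$timestamp <= ev$timestamp[i] + wc_window_min * 60
        if (has_id) inwin <- inwin & rt$animal_id == ev$animal_id[i]
        reason[inwin & is.na(reason)] <- "post_wc_event"
      }
    }
  }

  keep <- is.na(reason)
  rejected <- rt[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(retained = rt[keep, , drop = FALSE], rejected = rejected)
}

#' Collapse repeated bolus transmissions to one value per timestamp
#'
#' Rumen boluses retransmit a trailing history (the previous 11 ten-minute
#' readings) with every new transmission, so most readings arrive many
#' times. This keeps exactly one record per `(animal_id, timestamp)`:
#' identical duplicates collapse silently; where retransmissions disagree,
#' the value from the latest transmission wins (retransmission is treated
#' as a correction channel) and the conflict is logged.
#'
#' @param records Tibble with `animal_id`, `timestamp`, `value`, and
#'   `transmission_id` (sortable; later id = later transmission).
#' @return List with `unique` (one row per animal-timestamp, chronological)
#'   and `conflicts` (one row per conflicting animal-timestamp, with
#'   `n_values` distinct values seen and the `value` retained).
#' @export
dedupe_bolus_transmissions <- function(records) {
  need <- c("animal_id", "timestamp", "value", "transmission_id")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  records <- dplyr::arrange(tibble::as_tibble(records),
                            .data$animal_id, .data$timestamp,
                            .data$transmission_id)
  grp <- dplyr::group_by(records, .data$animal_id, .data$timestamp)
  uniq <- dplyr::summarise(
    grp,
    n_values = dplyr::n_distinct(.data$value),
    value = .data$value[dplyr::n()],   # latest transmission wins
    .groups = "drop")
  conflicts <- uniq[uniq$n_values > 1L,
                    c("animal_id", "timestamp", "n_values", "value")]
  uniq$n_values <- NULL
  list(unique = uniq, conflicts = conflicts)
}

#' Pair-offering feed rule
#'
#' Both members of a weight-matched pair are offered, on the same day, the
#' thermally challenged (TC) member's previous-day intake plus an uplift
#' (default 20%): if a TC animal ate 5 kg on day 6 it (and its pair) is
#' offered 6 kg on day 7.
#'
#' @param prev_day_intake_tc Previous-day TC intake, kg (>= 0). Vectorized.
#' @param uplift Proportional uplift, default 0.20.
#' @return Amount offered, kg.
#' @export
pair_offer <- function(prev_day_intake_tc, uplift = 0.20) {
  stopifnot(is.numeric(prev_day_intake_tc))
  if (any(prev_day_intake_tc < 0, na.rm = TRUE)) {
    stop("previous-day intake must be non-negative", call. = FALSE)
  }
  prev_day_intake_tc * (1 + uplift)
}

#' Gradual step-down of a feed-restricted offer
#'
#' When the TC member of a pair suddenly drops its intake, the restricted
#' (FRTN) member's offer is stepped down gradually rather than cut at once:
#' each day the offer falls by at most `max_daily_drop` until it reaches the
#' TC-derived target.
#'
#' @param frtn_prev_offer Previous FRTN offer, kg.
#' @param tc_target Target offer derived from the TC pair, kg.
#' @param max_daily_drop Maximum permitted single-day reduction, kg.
#' @return Today's offer: `max(tc_target, frtn_prev_offer - max_daily_drop)`.
#' @export
step_down_offer <- function(frtn_prev_offer, tc_target, max_daily_drop) {
  stopifnot(is.numeric(frtn_prev_offer), is.numeric(tc_target),
            is.numeric(max_daily_drop))
  if (any(c(frtn_prev_offer, tc_target, max_daily_drop) < 0)) {
    stop("offers and drop limits must be non-negative", call. = FALSE)
  }
  pmax(tc_target, frtn_prev_offer - max_daily_drop)
}

#' Dry-matter intake from a feed ledger
#'
#' DMI = (offered - refusals) x DM fraction, with the fixed chaff component
#' handled per `chaff_policy`: `"assume_consumed"` adds the constant chaff
#' DM in full (refusals are attributed to the grain ration);
#' `"prorate_refusals"` scales the chaff by the consumed fraction of the
#' offer. Refusal DM uses the diet DM fraction.
#'
#' @param ledger Tibble with `animal_id`, `day`, `offered_asfed_kg`,
#'   `refusals_asfed_kg`, `dm_fraction` (0-1).
#' @param chaff_dm_kg Constant chaff allocation, kg DM per day.
#' @param chaff_policy One of `"assume_consumed"`, `"prorate_refusals"`.
#' @return The ledger with a `dmi` column (kg DM per animal per day).
#' @export
compute_dmi <- function(ledger, chaff_dm_kg = 1.08,
                        chaff_policy = c("assume_consumed",
                                         "prorate_refusals")) {
  chaff_policy <- match.arg(chaff_policy)
  need <- c("animal_id", "day", "offered_asfed_kg", "refusals_asfed_kg",
            "dm_fraction")
  stopifnot(is.data.frame(ledger), all(need %in% names(ledger)))
  bad <- ledger$refusals_asfed_kg < 0 |
    ledger$refusals_asfed_kg > ledger$offered_asfed_kg
  if (any(bad, na.rm = TRUE)) {
    stop("refusals must lie in [0, offered]", call. = FALSE)
  }
  grain_dm <- (ledger$offered_asfed_kg - ledger$refusals_asfed_kg) *
    ledger$dm_fraction
  chaff <- switch(chaff_policy,
    assume_consumed = chaff_dm_kg,
    prorate_refusals = chaff_dm_kg *
      ifelse(ledger$offered_asfed_kg > 0,
             1 - ledger$refusals_asfed_kg / ledger$offered_asfed_kg, 1))
  ledger$dmi <- grain_dm + chaff
  tibble::as_tibble(ledger)
}

#' Daily water consumption from cumulative meter readings
#'
#' Water meters are cumulative; a day's consumption is the day's last
#' reading minus the previous day's last reading (the first day uses the
#' day-start baseline, i.e. its own first reading). Decreasing meter values
#' are a recording error and rejected.
#'
#' @param meter Tibble with `animal_id`, `day`, `timestamp`, `reading_l`
#'   (cumulative litres).
#' @return Tibble `animal_id`, `day`, `wc` (litres per day).
#' @export
compute_wc <- function(meter) {
  need <- c("animal_id", "day", "timestamp", "reading_l")
  stopifnot(is.data.frame(meter), all(need %in% names(meter)))
  meter <- dplyr::arrange(tibble::as_tibble(meter),
                          .data$animal_id, .data$timestamp)
  by_animal <- dplyr::group_by(meter, .data$animal_id)
  dec <- dplyr::filter(by_animal, c(FALSE, diff(.data$reading_l) < 0))
  if (nrow(dec) > 0L) {
    stop(sprintf(
      "water meter decreased for animal %s at %s",
      dec$animal_id[1], format(dec$timestamp[1])), call. = FALSE)
  }
  closes <- dplyr::summarise(
    dplyr::group_by(meter, .data$animal_id, .data$day),
    day_open = .data$reading_l[1L],
    day_close = .data$reading_l[dplyr::n()],
    .groups = "drop")
  closes <- dplyr::arrange(closes, .data$animal_id, .data$day)
  closes <- dplyr::mutate(
    dplyr::group_by(closes, .data$animal_id),
    prev_close = dplyr::lag(.data$day_close),
    wc = .data$day_close -
      dplyr::coalesce(.data$prev_close, .data$day_open))
  dplyr::ungroup(closes)[, c("animal_id", "day", "wc")]
}

#' Assign trial period labels to day indices
#'
#' Pre-Challenge covers days up to 4, Challenge days 5-11, Recovery days 12
#' onward; days 4 and 12 are additionally flagged as transition days.
#'
#' @param day Integer vector of day indices.
#' @return Tibble with `period` (factor Pre-Challenge/Challenge/Recovery)
#'   and `transition` (logical).
#' @export
assign_period <- function(day) {
  period <- cut(day, breaks = c(-Inf, 4, 11, Inf),
                labels = c("PreChallenge", "Challenge", "Recovery"),
                right = TRUE)
  tibble::tibble(period = period, transition = day %in% c(4L, 12L))
}

#' Aggregate cleaned observations to per-animal daily summaries
#'
#' Converts sanitized, deduplicated long-format physiological records to one
#' row per animal-day holding the arithmetic mean of each measure's retained
#' records (with the contributing count stored alongside), merged with the
#' feed ledger's DMI, daily water consumption, and live weight on weigh
#' days. An animal-day with no retained records for a measure yields a
#' missing value, never zero.
#'
#' @param records Long tibble: `animal_id`, `treatment`, `day`, `timestamp`,
#'   `measure` (one of RT, RR, PS, ST_head, ST_shoulder, ST_rump, ST_leg),
#'   `value`. `WC_meter` rows, if present, are routed to [compute_wc()].
#' @param feed Feed ledger as accepted by [compute_dmi()], or a tibble
#'   already carrying `animal_id`, `day`, `dmi`.
#' @param lw Optional tibble `animal_id`, `day`, `lw_kg`.
#' @param hourly Logical; also return hourly means keyed by
#'   `(animal_id, day, hour)`.
#' @return Tibble with one row per animal-day: `mean_<measure>` and
#'   `n_<measure>` columns, `wc`, `dmi`, `lw`, `period`, `transition`.
#'   With `hourly = TRUE`, a list with elements `daily` and `hourly`.
#' @export
aggregate_daily <- function(records, feed = NULL, lw = NULL,
                            hourly = FALSE) {
  need <- c("animal_id", "day", "measure", "value")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  records <- tibble::as_tibble(records)

  wc_tbl <- NULL
  is_meter <- records$measure == "WC_meter"
  if (any(is_meter)) {
    meter <- records[is_meter, ]
    meter$reading_l <- meter$value
    wc_tbl <- compute_wc(meter)
    records <- records[!is_meter, ]
  }

  # canonical ordering so output layout is independent of input row order
  records <- dplyr::arrange(records, .data$measure, .data$animal_id,
                            .data$day)
  carry <- intersect(c("treatment", "cohort", "pair_id"), names(records))
  ids <- dplyr::distinct(records[, c("animal_id", carry), drop = FALSE])

  means <- dplyr::summarise(
    dplyr::group_by(records, .data$animal_id, .data$day, .data$measure),
    mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  daily <- tidyr::pivot_wider(
    means, id_cols = c("animal_id", "day"),
    names_from = "measure", values_from = c("mean", "n"),
    names_glue = "{.value}_{tolower(measure)}")

  if (!is.null(wc_tbl)) daily <- dplyr::left_join(
    daily, wc_tbl, by = c("animal_id", "day"))
  if (!is.null(feed)) {
    if (!"dmi" %in% names(feed)) feed <- compute_dmi(feed)
    daily <- dplyr::left_join(daily, feed[, c("animal_id", "day", "dmi")],
                              by = c("animal_id", "day"))
  }
  if (!is.null(lw)) {
    daily <- dplyr::left_join(daily, lw[, c("animal_id", "day", "lw_kg")],
                              by = c("animal_id", "day"))
  }
  daily <- dplyr::left_join(daily, ids, by = "animal_id")
  daily <- dplyr::bind_cols(daily, assign_period(daily$day))
  daily <- dplyr::arrange(daily, .data$animal_id, .data$day)

  if (!hourly) return(daily)

  if (!"timestamp" %in% names(records)) {
    stop("hourly aggregation needs a `timestamp` column", call. = FALSE)
  }
  records$hour <- as.integer(format(records$timestamp, "%H"))
  hmeans <- dplyr::summarise(
    dplyr::group_by(records, .data$animal_id, .data$day, .data$hour,
                    .data$measure),
    mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  hourly_tbl <- tidyr::pivot_wider(
    hmeans, id_cols = c("animal_id", "day", "hour"),
    names_from = "measure", values_from = c("mean", "n"),
    names_glue = "{.value}_{tolower(measure)}")
  list(daily = daily, hourly = hourly_tbl)
}

#' Read tidy long-format observation records
#'
#' @param path CSV with columns `animal_id`, `treatment`, `cohort`,
#'   `pair_id`, `timestamp`, `measure`, `value`.
#' @return Tibble with typed columns and a derived integer `day` column
#'   taken from the date part of `timestamp` relative to `day1_date` when
#'   supplied, otherwise from a `day` column if present.
#' @param day1_date Optional `Date`: calendar date of trial day 1.
#' @export
read_observations_csv <- function(path, day1_date = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, tz = "UTC")
  if (!is.null(day1_date)) {
    x$day <- as.integer(as.Date(x$timestamp) - as.Date(day1_date)) + 1L
  }
  if (!"day" %in% names(x)) {
    stop("observations need a `day` column or a `day1_date`", call. = FALSE)
  }
  tibble::as_tibble(x)
}
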