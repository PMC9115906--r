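#' Temperature-humidity index (THI)
#'
#' Computes the livestock heat-stress THI from air temperature and relative
#' humidity:
#' \deqn{THI = 0.8\,TA + (RH/100)(TA - 14.3) + 46.3}
#' the formulation underlying the Livestock Weather Safety Index. THI is
#' strictly increasing in `ta` and increasing in `rh` only when `ta`
#' exceeds 14.3 degrees C (below that the humidity term is negative).
#'
#' @param ta Air temperature, degrees C. Vectorized.
#' @param rh Relative humidity, percent (0-100). Vectorized; recycled
#'   against `ta`.
#' @return Numeric vector of THI values (dimensionless).
#' @examples
#' compute_thi(20.34, 71.51) # ~66.9, thermoneutral
#' compute_thi(30, 50)       # 77.15, Alert band
#' @export
compute_thi <- function(ta, rh) {
  stopifnot(is.numeric(ta), is.numeric(rh))
  if (any(!is.finite(ta))) stop("`ta` must be finite", call. = FALSE)
  bad <- !is.finite(rh) | rh < 0 | rh > 100
  if (any(bad)) {
    stop(sprintf("`rh` must lie in [0, 100]; offending value(s): %s",
                 paste(utils::head(rh[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  0.8 * ta + (rh / 100) * (ta - 14.3) + 46.3
}

#' Livestock Weather Safety Index category of a THI value
#'
#' Maps THI to the four advisory bands. The printed bands are integer-valued
#' with gaps (Normal <= 74; Alert 75-78; Danger 79-83; Emergency >= 84);
#' continuous THI is classified by the half-open extension
#' (-Inf, 74], (74, 78], (78, 83], (83, Inf) so every real value maps to
#' exactly one category.
#'
#' @param thi Numeric vector of THI values.
#' @return Ordered factor with levels `Normal < Alert < Danger < Emergency`.
#' @examples
#' classify_thi(c(70, 74, 77, 80, 84))
#' @export
classify_thi <- function(thi) {
  stopifnot(is.numeric(thi))
  if (any(!is.finite(thi))) stop("`thi` must be finite", call. = FALSE)
  cut(thi, breaks = c(-Inf, 74, 78, 83, Inf),
      labels = c("Normal", "Alert", "Danger", "Emergency"),
      right = TRUE, ordered_result = TRUE)
}

#' Diurnal climate program for a challenge day
#'
#' Builds the 24-hour set-point schedule used during the Challenge period of
#' a climate-controlled-room trial: conditions ramp up hourly from
#' `ramp_up_start` so that the daily maximum is reached at `plateau_start`
#' and held until `plateau_end`, then decrease hourly to reach the daily
#' minimum at `trough_reach`, which holds overnight. Ramps are
#' piecewise-linear in both TA and RH, evaluated on the hour.
#'
#' @param day_min Numeric length-2 vector `c(ta, rh)`: overnight minimum air
#'   temperature (degrees C) and relative humidity (percent).
#' @param day_max Numeric length-2 vector `c(ta, rh)`: daily maximum.
#' @param ramp_up_start,plateau_start,plateau_end,trough_reach Clock hours
#'   (0-23) of the schedule anchors; must be strictly increasing.
#' @return A tibble of class `diurnal_program` with columns `hour` (0-23),
#'   `ta`, `rh` and `thi` (THI of the hourly target pair).
#' @examples
#' prog <- build_diurnal_program(c(25, 40), c(35, 60))
#' prog[prog$hour == 12, ] # plateau: (35, 60)
#' @export
build_diurnal_program <- function(day_min, day_max,
                                  ramp_up_start = 7L, plateau_start = 9L,
                                  plateau_end = 16L, trough_reach = 20L) {
  stopifnot(length(day_min) == 2L, length(day_max) == 2L,
            is.numeric(day_min), is.numeric(day_max))
  if (day_min[1] > day_max[1] || day_min[2] > day_max[2]) {
    stop("`day_min` must not exceed `day_max` componentwise", call. = FALSE)
  }
  sched <- c(ramp_up_start, plateau_start, plateau_end, trough_reach)
  if (any(diff(sched) <= 0) || any(sched < 0) || any(sched > 23)) {
    stop("schedule hours must be strictly increasing within 0-23",
         call. = FALSE)
  }
  # anchor profile over one day; trough holds through midnight wrap-around
  anchors_h <- c(0, ramp_up_start, plateau_start, plateau_end,
                 trough_reach, 23)
  interp_one <- function(lo, hi) {
    anchors_v <- c(lo, lo, hi, hi, lo, lo)
    stats::approx(anchors_h, anchors_v, xout = 0:23, method = "linear")$y
  }
  ta <- interp_one(day_min[1], day_max[1])
  rh <- interp_one(day_min[2], day_max[2])
  out <- tibble::tibble(hour = 0:23, ta = ta, rh = rh,
                        thi = compute_thi(ta, rh))
  class(out) <- c("diurnal_program", class(out))
  out
}

#' THI aggregation over a set of climate readings
#'
#' A day's THI can be summarized either as the mean of instantaneous THI
#' values ("mean of THI") or as the THI of the mean TA and mean RH ("THI of
#' means"); the two differ whenever TA and RH covary. Both are returned so
#' the choice is always explicit.
#'
#' @param ta,rh Numeric vectors of paired instantaneous readings.
#' @return Named list with `mean_of_thi` and `thi_of_means`.
#' @export
summarize_thi <- function(ta, rh) {
  stopifnot(length(ta) == length(rh), length(ta) >= 1L)
  list(mean_of_thi = mean(compute_thi(ta, rh)),
       thi_of_means = compute_thi(mean(ta), mean(rh)))
}

#' Read a climate CSV
#'
#' Expects columns `timestamp` (ISO-8601), `ta_c`, `rh_pct`; appends derived
#' `thi` and `category` columns.
#'
#' @param path Path to the CSV file.
#' @return Tibble with `timestamp`, `ta_c`, `rh_pct`, `thi`, `category`.
#' @export
read_climate_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         timestamp = readr::col_datetime(),
                         ta_c = readr::col_double(),
                         rh_pct = readr::col_double()))
  x$thi <- compute_thi(x$ta_c, x$rh_pct)
  x$category <- classify_thi(x$thi)
  x
}

#' Write a climate table with derived THI columns
#'
#' @param x Tibble with `timestamp`, `ta_c`, `rh_pct` (any further columns
#'   are preserved); `thi` and `category` are (re)computed before writing.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(x, path) {
  x$thi <- compute_thi(x$ta_c, x$rh_pct)
  x$category <- as.character(classify_thi(x$thi))
  readr::write_csv(x, path)
  invisible(path)
}
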