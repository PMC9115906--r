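#' Simple linear regression of one bivariate relationship
#'
#' Ordinary least-squares fit of `y` on `x` with Pearson correlation and
#' the two-sided t-test p-value on the slope, labelled with the field's
#' significance convention: `"significant"` for p < 0.05, `"tendency"` for
#' p in [0.05, 0.08], `"ns"` otherwise. Daily means are treated as
#' independent observations, which ignores their serial correlation; the
#' `caveat` field records this.
#'
#' @param x,y Numeric vectors of equal length (n >= 2); `x` needs nonzero
#'   variance. With exactly two points the line is determined but carries
#'   no inference: `slope_se` and `p_value` are `NA` and `label` is
#'   `"exact"`.
#' @param x_name,y_name,group Labels carried into the result.
#' @return One-row tibble: `x_name`, `y_name`, `group`, `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `n`, `x_min`, `x_max`, `label`,
#'   `caveat`.
#' @export
fit_line <- function(x, y, x_name = "x", y_name = "y", group = "pooled") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) {
    abort(sprintf("linear fit needs >= 2 complete pairs, got %d", n),
          class = "heatloop_insufficient_data")
  }
  if (stats::sd(x) == 0) {
    abort("`x` is constant; slope undefined",
          class = "heatloop_rank_error")
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  if (n == 2L) {
    # the line is determined exactly; no residual df, so no inference
    se <- NA_real_; p <- NA_real_
    r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
    label <- "exact"
  } else {
    # summary.lm warns on numerically perfect fits; those are legitimate
    # inputs here (exact worked examples), so silence that warning
    sm <- suppressWarnings(summary(fit))
    se <- sm$coefficients["x", "Std. Error"]
    p <- if (stats::sd(y) == 0) 1 else sm$coefficients["x", "Pr(>|t|)"]
    r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
    label <- if (p < 0.05) "significant" else
      if (p <= 0.08) "tendency" else "ns"
  }
  tibble::tibble(
    x_name = x_name, y_name = y_name, group = group,
    slope = unname(cf["x"]), intercept = unname(cf["(Intercept)"]),
    slope_se = se,
    pearson_r = r, p_value = p, n = n,
    x_min = min(x), x_max = max(x), label = label,
    caveat = "daily means treated as independent observations")
}

#' Predict from a linear fit, flagging extrapolation
#'
#' @param fit One-row tibble from [fit_line()].
#' @param x New x values.
#' @return Tibble `x`, `y_hat`, `extrapolated` (outside the observed
#'   x-range).
#' @export
predict_line <- function(fit, x) {
  tibble::tibble(
    x = x,
    y_hat = fit$intercept + fit$slope * x,
    extrapolated = x < fit$x_min | x > fit$x_max)
}

default_battery_spec <- function() {
  tibble::tribble(
    ~x, ~y,
    "thi_max",       "mean_rt",
    "thi_min",       "mean_rt",
    "ta_max",        "mean_rt",
    "ta_min",        "mean_rt",
    "mean_rt",       "dmi",
    "mean_rt",       "lw_kg",
    "mean_rt",       "mean_rr",
    "mean_rt",       "mean_ps",
    "mean_rt",       "mean_st_head",
    "mean_rt",       "wc")
}

#' Battery of daily-mean linear relationships
#'
#' Runs [fit_line()] for every (x, y) pair of the spec, per treatment group
#' and pooled across groups (group daily means concatenated, unweighted).
#' The default spec reproduces the standard heat-load battery: daily mean
#' rumen temperature (RT) against daily max/min THI and air temperature,
#' and DMI, live weight, respiration rate, panting score, head surface
#' temperature and water consumption against RT.
#'
#' The battery operates on group-level daily means: per-animal daily
#' summaries are first averaged across animals within `(group, day)`.
#' Climate columns (`thi_max` etc.), if used by the spec, must already be
#' joined onto the summaries by day.
#'
#' @param daily Tibble of per-animal daily summaries (see
#'   [aggregate_daily()]) with a `treatment` column, or already group-level
#'   daily means if `pre_averaged = TRUE`.
#' @param spec Two-column tibble (`x`, `y`) of column names; default
#'   [default_battery_spec()] restricted to columns present.
#' @param pre_averaged Set TRUE when `daily` already holds one row per
#'   (treatment, day).
#' @param drop_day1_wc Exclude day 1 from WC fits (drinker-training
#'   inflation); default FALSE.
#' @return Tibble of [fit_line()] rows, one per (pair, group) plus pooled;
#'   pairs whose columns are absent are skipped with a message.
#' @export
run_battery <- function(daily, spec = NULL, pre_averaged = FALSE,
                        drop_day1_wc = FALSE) {
  stopifnot(is.data.frame(daily), "treatment" %in% names(daily))
  if (is.null(spec)) spec <- default_battery_spec()

  if (!pre_averaged) {
    num_cols <- setdiff(names(daily)[vapply(daily, is.numeric, TRUE)],
                        c("day", "cohort"))
    daily <- dplyr::summarise(
      dplyr::group_by(daily, .data$treatment, .data$day),
      dplyr::across(dplyr::all_of(num_cols), ~mean(.x, na.rm = TRUE)),
      .groups = "drop")
  }

  groups <- unique(as.character(daily$treatment))
  out <- list()
  for (i in seq_len(nrow(spec))) {
    xn <- spec$x[i]; yn <- spec$y[i]
    if (!xn %in% names(daily) || !yn %in% names(daily)) {
      message(sprintf("battery: skipping %s ~ %s (column missing)", yn, xn))
      next
    }
    dat <- daily
    if (drop_day1_wc && "wc" %in% c(xn, yn)) dat <- dat[dat$day != 1L, ]
    for (g in c(groups, if (length(groups) > 1L) "pooled")) {
      sub <- if (g == "pooled") dat else dat[dat$treatment == g, ]
      xv <- sub[[xn]]; yv <- sub[[yn]]
      if (sum(is.finite(xv) & is.finite(yv)) < 3L) next
      res <- tryCatch(fit_line(xv, yv, x_name = xn, y_name = yn, group = g),
                      heatloop_rank_error = function(e) NULL)
      if (!is.null(res)) out[[length(out) + 1L]] <- res
    }
  }
  dplyr::bind_rows(out)
}

#' Per-day group contrasts
#'
#' Welch two-sample comparison of the two treatment arms for each day and
#' measure: mean difference (first group minus second), standard error of
#' the difference, and the two-sided Welch p-value. No multiplicity
#' correction by default; `adjust = "holm"` applies a Holm adjustment per
#' measure across days. When either arm has fewer than 2 animals or zero
#' variance on a day the difference is still reported but the test is
#' suppressed (`p_value` NA with a flag).
#'
#' @param daily Per-animal daily summaries with `treatment`.
#' @param measures Character vector of summary columns to contrast;
#'   defaults to all numeric `mean_*`, `dmi`, `wc`, `lw_kg` columns present.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Tibble: `measure`, `day`, `diff`, `se`, `p_value`, `flag`.
#' @export
per_day_contrast <- function(daily, measures = NULL,
                             adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot("treatment" %in% names(daily))
  grps <- sort(unique(as.character(daily$treatment)))
  if (length(grps) != 2L) {
    abort("per_day_contrast needs exactly two treatment groups",
          class = "heatloop_validation")
  }
  if (is.null(measures)) {
    measures <- intersect(
      c(grep("^mean_", names(daily), value = TRUE), "dmi", "wc", "lw_kg"),
      names(daily)[vapply(daily, is.numeric, TRUE)])
  }
  rows <- list()
  for (m in measures) {
    for (d in sort(unique(daily$day))) {
      a <- daily[[m]][daily$day == d & daily$treatment == grps[1]]
      b <- daily[[m]][daily$day == d & daily$treatment == grps[2]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) == 0L || length(b) == 0L) next
      diff <- mean(a) - mean(b)
      if (length(a) < 2L || length(b) < 2L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          measure = m, day = d, diff = diff, se = NA_real_,
          p_value = NA_real_, flag = "single_animal_group")
      } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          measure = m, day = d, diff = diff, se = 0,
          p_value = if (diff == 0) 1 else NA_real_,
          flag = if (diff == 0) "identical_groups" else "variance_zero")
      } else {
        tt <- stats::t.test(a, b)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          measure = m, day = d, diff = diff,
          se = unname(tt$stderr), p_value = tt$p.value, flag = "ok")
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (adjust == "holm" && nrow(out) > 0L) {
    out <- dplyr::mutate(
      dplyr::group_by(out, .data$measure),
      p_value = ifelse(is.na(.data$p_value), NA,
                       stats::p.adjust(.data$p_value, method = "holm")))
    out <- dplyr::ungroup(out)
  }
  out
}
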