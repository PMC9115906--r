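# Independent oracles used across test files. These deliberately re-derive
# quantities by different routes than the package implementation.

# Naive responding-variable R^2: branches of the conic in y obtained with
# polyroot() (independent quadratic solver), nearest branch per point,
# sums of squares recomputed from first principles.
naive_response_r2 <- function(points, fit) {
  cf <- fit$coef
  g <- heatloop::conic_to_geometry(fit)
  xlo <- g$x_min_point[["x"]]; xhi <- g$x_max_point[["x"]]
  pred <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    x <- points$x[i]; yo <- points$y[i]
    if (x < xlo) { pred[i] <- g$x_min_point[["y"]]; next }
    if (x > xhi) { pred[i] <- g$x_max_point[["y"]]; next }
    # c y^2 + (b x + e) y + (a x^2 + d x + f) = 0, solved via polyroot
    rts <- polyroot(c(cf[["a"]] * x^2 + cf[["d"]] * x + cf[["f"]],
                      cf[["b"]] * x + cf[["e"]], cf[["c"]]))
    ys <- sort(Re(rts))
    d1 <- abs(yo - ys[1]); d2 <- abs(yo - ys[2])
    pred[i] <- if (d2 <= d1) ys[2] else ys[1]
  }
  1 - sum((points$y - pred)^2) / sum((points$y - mean(points$y))^2)
}

# Dense parametric sampling of an ellipse from its geometric parameters.
dense_ellipse_samples <- function(geom, n = 1e5) {
  t <- seq(0, 2 * pi, length.out = n)
  # reconstruct axis orientation: rotation is the major-axis angle
  px <- geom$semi_major * cos(t); py <- geom$semi_minor * sin(t)
  r <- geom$rotation
  data.frame(
    x = geom$center[["x0"]] + px * cos(r) - py * sin(r),
    y = geom$center[["y0"]] + px * sin(r) + py * cos(r))
}

# Textbook Welch two-sample test computed from explicit formulas.
welch_oracle <- function(a, b) {
  m <- mean(a) - mean(b)
  va <- var(a) / length(a); vb <- var(b) / length(b)
  se <- sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  t <- m / se
  list(diff = m, se = se, p = 2 * pt(-abs(t), df))
}

# Shared small simulated cohort reused by several test files (generation
# is deterministic, so building it once is safe).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- heatloop::simulate_cohort(
        heatloop::sim_config(n_pairs = 4L, seed = 42L))
    }
    cache
  }
})

default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- heatloop::simulate_cohort(heatloop::sim_config(seed = 101L))
    }
    cache
  }
})

daily_from_sim <- function(sim) {
  heatloop::aggregate_daily(sim$observations, feed = sim$feed, lw = sim$lw)
}

group_day_means <- function(daily) {
  out <- dplyr::summarise(
    dplyr::group_by(daily, treatment, day),
    rt = mean(mean_rt, na.rm = TRUE),
    dmi = mean(dmi, na.rm = TRUE), .groups = "drop")
  dplyr::arrange(out, treatment, day)
}
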