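test_that("noiseless canonical ellipse is recovered to 1e-9", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  fit <- fit_conic(cbind(2 * cos(th), sin(th)))  # x^2/4 + y^2 = 1
  expect_true(fit$is_ellipse)
  expect_lt(fit$discriminant, 0)
  cf <- fit$coef / (-fit$coef[["f"]])            # scale so f = -1
  expect_equal(unname(cf), c(1 / 4, 0, 1, 0, 0, -1), tolerance = 1e-9)
})

test_that("degenerate inputs raise classed errors", {
  expect_error(fit_conic(cbind(1:5, (1:5)^2)),
               class = "heatloop_insufficient_data")
  expect_error(fit_conic(cbind(1:10, 2 * (1:10) + 1)),
               class = "heatloop_rank_error")
  expect_error(fit_conic(cbind(1:10, rep(1, 10))),
               class = "heatloop_rank_error")
})

test_that("round-trip: sample known geometry, refit, recover to 1e-6", {
  pts <- sample_ellipse(c(39.9, 9.1), semi_major = 2.1, semi_minor = 0.7,
                        rotation = 0.4, n = 18)
  g <- conic_to_geometry(fit_conic(pts))
  expect_equal(unname(g$center), c(39.9, 9.1), tolerance = 1e-6)
  expect_equal(g$semi_major, 2.1, tolerance = 1e-6)
  expect_equal(g$semi_minor, 0.7, tolerance = 1e-6)
  expect_equal(g$rotation, 0.4, tolerance = 1e-6)
  # tangency points satisfy the conic
  fit <- fit_conic(pts)
  for (p in list(g$y_max_point, g$y_min_point, g$x_max_point,
                 g$x_min_point)) {
    expect_lt(abs(heatloop:::conic_value(fit$coef, p[["x"]], p[["y"]])),
              1e-8)
  }
})

test_that("unit circle geometry and traversal orientation", {
  pts <- sample_ellipse(c(0, 0), 1, 1, n = 12)
  g <- conic_to_geometry(fit_conic(pts))
  expect_equal(unname(g$center), c(0, 0), tolerance = 1e-9)
  expect_equal(g$semi_major, 1, tolerance = 1e-9)
  expect_equal(g$semi_minor, 1, tolerance = 1e-9)
  expect_equal(unname(g$y_max_point), c(0, 1), tolerance = 1e-7)
  # (1,0)->(0,1)->(-1,0)->(0,-1) is counterclockwise; reversed, clockwise
  quad <- data.frame(x = c(1, 0, -1, 0), y = c(0, 1, 0, -1))
  expect_equal(traversal_direction(quad), "counterclockwise")
  expect_equal(traversal_direction(quad[4:1, ]), "clockwise")
})

test_that("geometry is invariant to conic coefficient rescaling", {
  pts <- sample_ellipse(c(3, -2), 2, 1, rotation = 0.9, n = 14)
  fit <- fit_conic(pts)
  g1 <- conic_to_geometry(fit)
  fit2 <- fit
  fit2$coef <- fit$coef * 37.5   # same curve, different representation
  g2 <- conic_to_geometry(fit2)
  expect_equal(g1$center, g2$center, tolerance = 1e-10)
  expect_equal(g1$semi_major, g2$semi_major, tolerance = 1e-10)
  expect_equal(g1$rotation, g2$rotation, tolerance = 1e-10)
})

test_that("fit is equivariant under rotation and translation", {
  set.seed(7)
  pts <- sample_ellipse(c(39.9, 9.1), 0.7, 2.1, rotation = 0.4, n = 18,
                        noise_sd = 0.02)
  g1 <- conic_to_geometry(fit_conic(pts))
  for (ang in c(0.3, 1.1)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    shift <- c(-5, 12)
    moved <- sweep(as.matrix(pts) %*% t(R), 2, shift, "+")
    g2 <- conic_to_geometry(fit_conic(moved))
    expect_equal(unname(g2$center),
                 unname(as.vector(R %*% g1$center + shift)),
                 tolerance = 1e-8)
    expect_equal(g2$semi_major, g1$semi_major, tolerance = 1e-8)
    expect_equal(g2$semi_minor, g1$semi_minor, tolerance = 1e-8)
    rot_expect <- (g1$rotation + ang + pi / 2) %% pi - pi / 2
    rot_diff <- abs(g2$rotation - rot_expect) %% pi
    expect_lt(min(rot_diff, pi - rot_diff), 1e-8)
    expect_equal(g2$direction, g1$direction)
  }
})

test_that("noisy parameter recovery: median error < 5% of semi-minor", {
  true <- list(center = c(39.9, 9.1), a = 2.1, b = 0.7, rot = 0.4)
  errs <- t(vapply(1:200, function(s) {
    pts <- sample_ellipse(true$center, true$a, true$b, true$rot,
                          n = 18, noise_sd = 0.02 * true$b, seed = s)
    g <- conic_to_geometry(fit_conic(pts))
    c(ctr = sqrt(sum((g$center - true$center)^2)),
      a = abs(g$semi_major - true$a), b = abs(g$semi_minor - true$b))
  }, numeric(3)))
  tol <- 0.05 * true$b
  expect_lt(median(errs[, "ctr"]), tol)
  expect_lt(median(errs[, "a"]), tol)
  expect_lt(median(errs[, "b"]), tol)
})

test_that("tangency extrema agree with a dense parametric oracle", {
  pts <- sample_ellipse(c(39.9, 9.1), 2.1, 0.7, rotation = 0.4, n = 18)
  g <- conic_to_geometry(fit_conic(pts))
  dense <- dense_ellipse_samples(g, n = 1e5)
  expect_equal(g$y_max_point[["y"]], max(dense$y), tolerance = 1e-6)
  expect_equal(g$y_min_point[["y"]], min(dense$y), tolerance = 1e-6)
  expect_equal(g$x_max_point[["x"]], max(dense$x), tolerance = 1e-6)
  expect_equal(g$x_min_point[["x"]], min(dense$x), tolerance = 1e-6)
  # y_max dominates every sample
  expect_true(all(dense$y <= g$y_max_point[["y"]] + 1e-6))
})

test_that("direction flips under time reversal, over random loops", {
  for (s in 1:25) {
    pts <- sample_ellipse(c(runif(1, -5, 5), runif(1, -5, 5)),
                          runif(1, 1, 3), runif(1, 0.3, 0.9),
                          rotation = runif(1, -1.4, 1.4), n = 12,
                          noise_sd = 0.02, seed = s)
    fwd <- traversal_direction(pts)
    rev <- traversal_direction(pts[nrow(pts):1, ])
    expect_true(fwd %in% c("clockwise", "counterclockwise"))
    expect_equal(rev, setdiff(c("clockwise", "counterclockwise"), fwd))
  }
  # collinear trajectory is undetermined
  expect_equal(traversal_direction(cbind(1:6, 2 * (1:6))), "undetermined")
})

test_that("sampled clockwise order is labelled clockwise", {
  cw <- sample_ellipse(c(0, 0), 2, 1, n = 10, direction = "clockwise")
  expect_equal(traversal_direction(cw), "clockwise")
  ccw <- sample_ellipse(c(0, 0), 2, 1, n = 10)
  expect_equal(traversal_direction(ccw), "counterclockwise")
})

test_that("R^2 is 1 for noiseless points and degrades with noise", {
  pts <- sample_ellipse(c(39.9, 9.1), 2.1, 0.7, rotation = 0.4, n = 18)
  fit <- fit_conic(pts)
  r2 <- ellipse_r2(pts, fit)
  expect_equal(r2$r2_response, 1, tolerance = 1e-9)
  expect_equal(r2$r2_sampson, 1, tolerance = 1e-9)

  set.seed(9)
  noisy <- pts
  noisy$y <- noisy$y + rnorm(18, 0, 3)   # noise swamping the structure
  fitn <- fit_conic(noisy)
  expect_lt(ellipse_r2(noisy, fitn)$r2_response, 0.7)
})

test_that("response R^2 matches an independent naive implementation", {
  for (s in c(3, 14, 27)) {
    pts <- sample_ellipse(c(39.9, 9.1), 2.1, 0.7, rotation = 0.4,
                          n = 18, noise_sd = 0.1, seed = s)
    fit <- fit_conic(pts)
    mine <- ellipse_r2(pts, fit)$r2_response
    oracle <- naive_response_r2(pts, fit)
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("r2 and geometry refuse non-elliptical fits", {
  pts <- sample_ellipse(c(0, 0), 2, 1, n = 12)
  fit <- fit_conic(pts)
  fit$is_ellipse <- FALSE
  expect_error(conic_to_geometry(fit), class = "heatloop_non_elliptical")
  expect_error(ellipse_r2(pts, fit), class = "heatloop_non_elliptical")
})
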