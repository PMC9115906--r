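#' @importFrom rlang .data abort
NULL

as_xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 2L)
    tibble::tibble(x = points[, 1], y = points[, 2])
  } else {
    stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
    tibble::as_tibble(points)[, c("x", "y")]
  }
}

#' Direct least-squares ellipse-specific conic fit
#'
#' Fits the general conic \eqn{ax^2 + bxy + cy^2 + dx + ey + f = 0} to a
#' point set by least squares under the ellipse-specific constraint
#' \eqn{4ac - b^2 = 1}, solved through the numerically stabilized block
#' partition of the generalized eigenproblem (the scatter matrix is split
#' into quadratic and linear blocks so the reduced 3x3 problem is solved
#' directly). The constraint guarantees that any solution is an ellipse.
#'
#' For conditioning, points are internally centered at their mean and both
#' axes divided by a single pooled scale before solving; coefficients are
#' back-transformed to data units. The common (isotropic) scale keeps the
#' fit exactly equivariant under rotation and translation of the data.
#'
#' @param points Two-column matrix or data frame with columns `x`, `y`,
#'   in chronological order if traversal direction is of interest.
#' @return Object of class `conic_fit`: list with `coef` (named a..f,
#'   normalized so that `4ac - b^2 = 1` with `a > 0`), `discriminant`
#'   (\eqn{b^2 - 4ac}), `n_points`, `is_ellipse`, `conditioning`
#'   (centering/scale used), and `points` (the input, as a tibble).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' fit_conic(cbind(2 * cos(th), sin(th)))
#' @export
fit_conic <- function(points) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n < 6L) {
    abort(sprintf("ellipse fitting needs at least 6 points, got %d", n),
          class = "heatloop_insufficient_data")
  }
  if (stats::sd(pts$x) == 0 || stats::sd(pts$y) == 0) {
    abort("x and y must each have nonzero variance",
          class = "heatloop_rank_error")
  }
  mx <- mean(pts$x); my <- mean(pts$y)
  s <- sqrt(mean((pts$x - mx)^2 + (pts$y - my)^2))
  u <- (pts$x - mx) / s
  v <- (pts$y - my) / s

  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) {
    abort("degenerate point configuration (collinear or coincident points)",
          class = "heatloop_rank_error")
  }
  Tmat <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tmat
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eig <- eigen(M)
  vecs <- eig$vectors
  ok <- abs(Im(eig$values)) < 1e-8
  vecs <- Re(vecs[, ok, drop = FALSE])
  if (ncol(vecs) == 0L) {
    abort("no real solution to the constrained fit",
          class = "heatloop_rank_error")
  }
  cond_val <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  sel <- which(cond_val > 0)
  if (length(sel) == 0L) {
    diag_fit <- fit_conic_unconstrained(points)
    abort("no elliptical solution for these points",
          class = "heatloop_non_elliptical",
          unconstrained = diag_fit)
  }
  a1 <- vecs[, sel[1]]
  coef_s <- c(a1, as.numeric(Tmat %*% a1))

  coef <- transform_conic_coef(coef_s, mx, my, s, s)
  k <- 4 * coef[1] * coef[3] - coef[2]^2
  coef <- coef / sqrt(k)           # renormalize: 4ac - b^2 = 1
  if (coef[1] < 0) coef <- -coef   # sign convention a > 0
  names(coef) <- c("a", "b", "c", "d", "e", "f")

  disc <- coef["b"]^2 - 4 * coef["a"] * coef["c"]
  structure(list(
    coef = coef,
    discriminant = unname(disc),
    n_points = n,
    is_ellipse = conic_is_real_ellipse(coef),
    conditioning = list(center = c(mx, my), scale = s),
    points = pts
  ), class = "conic_fit")
}

# Back-transform conic coefficients fitted on u = (x - mx)/sx,
# v = (y - my)/sy to raw (x, y) units.
transform_conic_coef <- function(cf, mx, my, sx, sy) {
  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; F <- cf[6]
  a <- A / sx^2
  b <- B / (sx * sy)
  c <- C / sy^2
  d <- -2 * A * mx / sx^2 - B * my / (sx * sy) + D / sx
  e <- -B * mx / (sx * sy) - 2 * C * my / sy^2 + E / sy
  f <- A * mx^2 / sx^2 + B * mx * my / (sx * sy) + C * my^2 / sy^2 -
    D * mx / sx - E * my / sy + F
  c(a, b, c, d, e, f)
}

# Unconstrained algebraic fit (smallest singular vector of the design),
# kept as a diagnostic for non-elliptical point sets.
fit_conic_unconstrained <- function(points) {
  pts <- as_xy(points)
  mx <- mean(pts$x); my <- mean(pts$y)
  s <- sqrt(mean((pts$x - mx)^2 + (pts$y - my)^2))
  if (s == 0) abort("coincident points", class = "heatloop_rank_error")
  u <- (pts$x - mx) / s; v <- (pts$y - my) / s
  D <- cbind(u^2, u * v, v^2, u, v, 1)
  sv <- svd(D)
  cf <- sv$v[, ncol(sv$v)]
  coef <- transform_conic_coef(cf, mx, my, s, s)
  coef <- coef / sqrt(sum(coef^2))
  names(coef) <- c("a", "b", "c", "d", "e", "f")
  list(coef = coef,
       discriminant = unname(coef["b"]^2 - 4 * coef["a"] * coef["c"]))
}

conic_is_real_ellipse <- function(coef) {
  a <- coef[1]; b <- coef[2]; c <- coef[3]
  d <- coef[4]; e <- coef[5]; f <- coef[6]
  if (b^2 - 4 * a * c >= 0) return(FALSE)
  A33 <- matrix(c(a, b / 2, d / 2, b / 2, c, e / 2, d / 2, e / 2, f), 3, 3)
  if (abs(det(A33)) < 1e-14) return(FALSE)   # degenerate (point/lines)
  ctr <- solve(matrix(c(2 * a, b, b, 2 * c), 2, 2), -c(d, e))
  f0 <- a * ctr[1]^2 + b * ctr[1] * ctr[2] + c * ctr[2]^2 +
    d * ctr[1] + e * ctr[2] + f
  lam <- eigen(matrix(c(a, b / 2, b / 2, c), 2, 2), symmetric = TRUE)$values
  all(-f0 / lam > 0)                          # real (not imaginary) ellipse
}

#' Geometric parameters of a fitted ellipse
#'
#' Converts algebraic conic coefficients to center, semi-axes, rotation,
#' the four axis-aligned tangency points (predicted extrema of each
#' variable), and — when a chronological point sequence is available — the
#' traversal direction of the loop.
#'
#' The center solves the gradient system \eqn{2a x_0 + b y_0 + d = 0},
#' \eqn{b x_0 + 2c y_0 + e = 0}; axes and rotation come from the
#' eigen-decomposition of the quadratic-form matrix; horizontal-tangency
#' points solve \eqn{2a x + b y + d = 0} jointly with the conic and
#' vertical-tangency points solve \eqn{b x + 2c y + e = 0} jointly with it.
#'
#' @param fit A `conic_fit` with `is_ellipse` TRUE.
#' @param time_order Optional chronologically ordered points (defaults to
#'   the points stored in `fit`) used for the direction label.
#' @return Object of class `ellipse_geometry`: list with `center`
#'   (named x0, y0), `semi_major`, `semi_minor`, `rotation` (radians in
#'   (-pi/2, pi/2]), `y_max_point`, `y_min_point`, `x_max_point`,
#'   `x_min_point` (each named (x, y)), and `direction`.
#' @export
conic_to_geometry <- function(fit, time_order = NULL) {
  stopifnot(inherits(fit, "conic_fit"))
  if (!isTRUE(fit$is_ellipse)) {
    abort("conic_to_geometry requires an elliptical fit",
          class = "heatloop_non_elliptical")
  }
  cf <- fit$coef
  a <- unname(cf["a"]); b <- unname(cf["b"]); c <- unname(cf["c"])
  d <- unname(cf["d"]); e <- unname(cf["e"]); f <- unname(cf["f"])

  ctr <- solve(matrix(c(2 * a, b, b, 2 * c), 2, 2), -c(d, e))
  x0 <- ctr[1]; y0 <- ctr[2]
  f0 <- a * x0^2 + b * x0 * y0 + c * y0^2 + d * x0 + e * y0 + f

  S <- matrix(c(a, b / 2, b / 2, c), 2, 2)
  eg <- eigen(S, symmetric = TRUE)
  axes <- sqrt(-f0 / eg$values)         # one per eigenvalue
  imaj <- which.max(axes)
  semi_major <- axes[imaj]
  semi_minor <- axes[-imaj]
  vmaj <- eg$vectors[, imaj]
  rotation <- atan2(vmaj[2], vmaj[1])
  if (rotation <= -pi / 2) rotation <- rotation + pi
  if (rotation > pi / 2) rotation <- rotation - pi

  # horizontal tangents: x eliminated via 2a x + b y + d = 0
  qy <- solve_tangency(c - b^2 / (4 * a), e - b * d / (2 * a),
                       f - d^2 / (4 * a))
  hx <- -(b * qy + d) / (2 * a)
  y_pts <- list(c(x = hx[which.max(qy)], y = max(qy)),
                c(x = hx[which.min(qy)], y = min(qy)))
  # vertical tangents: y eliminated via b x + 2c y + e = 0
  qx <- solve_tangency(a - b^2 / (4 * c), d - b * e / (2 * c),
                       f - e^2 / (4 * c))
  vy <- -(b * qx + e) / (2 * c)
  x_pts <- list(c(x = max(qx), y = vy[which.max(qx)]),
                c(x = min(qx), y = vy[which.min(qx)]))

  pts <- if (is.null(time_order)) fit$points else as_xy(time_order)
  direction <- traversal_direction(pts)

  structure(list(
    center = c(x0 = unname(x0), y0 = unname(y0)),
    semi_major = unname(semi_major),
    semi_minor = unname(semi_minor),
    rotation = unname(rotation),
    y_max_point = y_pts[[1]], y_min_point = y_pts[[2]],
    x_max_point = x_pts[[1]], x_min_point = x_pts[[2]],
    direction = direction
  ), class = "ellipse_geometry")
}

solve_tangency <- function(A, B, C) {
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    if (disc > -1e-10 * max(B^2, 1)) disc <- 0 else
      abort("tangency solve failed: negative discriminant",
            class = "heatloop_non_elliptical")
  }
  r <- sqrt(disc)
  c((-B + r) / (2 * A), (-B - r) / (2 * A))
}

#' Evaluate the conic quadratic form at points
#'
#' @param coef Named coefficient vector a..f.
#' @param x,y Coordinates.
#' @return \eqn{ax^2 + bxy + cy^2 + dx + ey + f}.
#' @keywords internal
conic_value <- function(coef, x, y) {
  coef[["a"]] * x^2 + coef[["b"]] * x * y + coef[["c"]] * y^2 +
    coef[["d"]] * x + coef[["e"]] * y + coef[["f"]]
}

sampson_distance <- function(coef, x, y) {
  q <- conic_value(coef, x, y)
  gx <- 2 * coef[["a"]] * x + coef[["b"]] * y + coef[["d"]]
  gy <- coef[["b"]] * x + 2 * coef[["c"]] * y + coef[["e"]]
  q / sqrt(gx^2 + gy^2)
}

#' Goodness-of-fit of an ellipse to observed points
#'
#' Two R-squared definitions are computed and always reported together:
#'
#' * `r2_response` (primary): treats `y` as the responding variable. For
#'   each observed `x` within the ellipse's x-range, the fitted value is the
#'   ellipse branch (upper or lower) nearer the observed `y` (ties go to the
#'   upper branch); observed `x` outside the x-range is predicted at the
#'   nearer vertical-tangency point's `y`. Then
#'   \eqn{R^2 = 1 - SS_{res}/SS_{tot}} about the mean observed `y`.
#' * `r2_sampson` (secondary, algebraic): \eqn{1 - \sum d_i^2 / \sum
#'   \|p_i - \bar p\|^2} where \eqn{d_i} is the Sampson (first-order
#'   geometric) distance of point \eqn{i} to the conic and the denominator
#'   is the total squared scatter of the points about their centroid.
#'
#' @param points Observed points (chronology irrelevant here).
#' @param fit A `conic_fit` with `is_ellipse` TRUE.
#' @return List `r2_response`, `r2_sampson`, `n`. If the observed `y` has
#'   zero scatter the response R-squared is `NA` with a `degenerate` flag.
#' @export
ellipse_r2 <- function(points, fit) {
  stopifnot(inherits(fit, "conic_fit"))
  if (!isTRUE(fit$is_ellipse)) {
    abort("ellipse_r2 requires an elliptical fit",
          class = "heatloop_non_elliptical")
  }
  pts <- as_xy(points)
  if (nrow(pts) < 6L) {
    abort("ellipse_r2 needs at least 6 points",
          class = "heatloop_insufficient_data")
  }
  geom <- conic_to_geometry(fit, time_order = pts)
  cf <- fit$coef
  xlo <- geom$x_min_point[["x"]]; xhi <- geom$x_max_point[["x"]]

  pred <- vapply(seq_len(nrow(pts)), function(i) {
    x <- pts$x[i]; yobs <- pts$y[i]
    if (x < xlo) return(geom$x_min_point[["y"]])
    if (x > xhi) return(geom$x_max_point[["y"]])
    # branches: c y^2 + (b x + e) y + (a x^2 + d x + f) = 0
    A <- cf[["c"]]; B <- cf[["b"]] * x + cf[["e"]]
    C <- cf[["a"]] * x^2 + cf[["d"]] * x + cf[["f"]]
    disc <- max(B^2 - 4 * A * C, 0)
    roots <- sort(c((-B + sqrt(disc)) / (2 * A),
                    (-B - sqrt(disc)) / (2 * A)))
    dlo <- abs(yobs - roots[1]); dhi <- abs(yobs - roots[2])
    if (dhi <= dlo) roots[2] else roots[1]   # tie -> upper branch
  }, numeric(1))

  ss_tot <- sum((pts$y - mean(pts$y))^2)
  if (ss_tot == 0) {
    return(list(r2_response = NA_real_, r2_sampson = NA_real_,
                n = nrow(pts), degenerate = TRUE))
  }
  r2_resp <- 1 - sum((pts$y - pred)^2) / ss_tot

  ds <- sampson_distance(cf, pts$x, pts$y)
  scatter <- sum((pts$x - mean(pts$x))^2 + (pts$y - mean(pts$y))^2)
  r2_samp <- 1 - sum(ds^2) / scatter

  list(r2_response = r2_resp, r2_sampson = r2_samp, n = nrow(pts),
       degenerate = FALSE)
}

#' Traversal direction of a time-ordered planar loop
#'
#' Sign of the closed shoelace (signed polygon area) sum over the points in
#' chronological order, in the plotting frame (x rightward, y upward):
#' negative signed area is clockwise. A signed area below `tol` times the
#' squared point scatter is reported as undetermined (e.g. collinear
#' trajectories).
#'
#' @param points Chronologically ordered points.
#' @param tol Relative tolerance on the signed area.
#' @return One of `"clockwise"`, `"counterclockwise"`, `"undetermined"`.
#' @examples
#' traversal_direction(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0))) # clockwise
#' @export
traversal_direction <- function(points, tol = 1e-10) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n < 3L) return("undetermined")
  x <- pts$x; y <- pts$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area2 <- sum(x * yn - xn * y)
  scale2 <- sum((x - mean(x))^2 + (y - mean(y))^2)
  if (scale2 == 0 || abs(area2) <= tol * scale2) return("undetermined")
  if (area2 < 0) "clockwise" else "counterclockwise"
}

#' Fit and fully characterize a hysteresis loop
#'
#' Convenience wrapper chaining [fit_conic()], [conic_to_geometry()] and
#' [ellipse_r2()] on one chronologically ordered point set (e.g. daily
#' mean rumen temperature vs daily dry-matter intake).
#'
#' @param points Chronologically ordered points.
#' @return List with `fit`, `geometry`, `r2`.
#' @export
fit_ellipse_loop <- function(points) {
  fit <- fit_conic(points)
  list(fit = fit,
       geometry = conic_to_geometry(fit),
       r2 = ellipse_r2(points, fit))
}

#' Serialize an ellipse analysis to JSON
#'
#' @param loop Result of [fit_ellipse_loop()].
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
ellipse_to_json <- function(loop, path = NULL) {
  g <- loop$geometry
  obj <- list(
    coefficients = as.list(loop$fit$coef),
    discriminant = loop$fit$discriminant,
    n_points = loop$fit$n_points,
    conditioning = loop$fit$conditioning,
    center = as.list(g$center),
    semi_major = g$semi_major, semi_minor = g$semi_minor,
    rotation = g$rotation,
    y_max_point = as.list(g$y_max_point),
    y_min_point = as.list(g$y_min_point),
    x_max_point = as.list(g$x_max_point),
    x_min_point = as.list(g$x_min_point),
    direction = g$direction,
    r2_response = loop$r2$r2_response,
    r2_sampson = loop$r2$r2_sampson)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.conic_fit <- function(x, ...) {
  cat("Direct least-squares conic fit (constraint 4ac - b^2 = 1)\n")
  cat(sprintf("  n = %d points; discriminant b^2 - 4ac = %.6g; %s\n",
              x$n_points, x$discriminant,
              if (x$is_ellipse) "ellipse" else "not an ellipse"))
  print(round(x$coef, 6))
  invisible(x)
}

#' @export
print.ellipse_geometry <- function(x, ...) {
  cat(sprintf(
    "Ellipse: center (%.4g, %.4g), semi-axes %.4g / %.4g, rotation %.4g rad\n",
    x$center[1], x$center[2], x$semi_major, x$semi_minor, x$rotation))
  cat(sprintf("  y max %.4g at x = %.4g; y min %.4g at x = %.4g\n",
              x$y_max_point[["y"]], x$y_max_point[["x"]],
              x$y_min_point[["y"]], x$y_min_point[["x"]]))
  cat(sprintf("  traversal: %s\n", x$direction))
  invisible(x)
}
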