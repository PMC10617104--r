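#' Direct least-squares ellipse fit
#'
#' Fits the general conic \eqn{a x^2 + b x y + c y^2 + d x + e y + f = 0} to a
#' point set by minimizing the sum of squared algebraic distances subject to
#' the ellipse-specific constraint \eqn{4ac - b^2 = 1}. The solver uses the
#' numerically stabilized block decomposition of the direct method: the design
#' matrix is split into quadratic and linear coefficient blocks and the
#' constrained problem is reduced to a 3x3 eigenproblem, from which the unique
#' eigenvector satisfying the ellipse constraint is selected. Input points are
#' mean-centered and isotropically scaled before solving; coefficients are
#' mapped back to the original frame and rescaled so that \eqn{4ac - b^2 = 1}
#' holds exactly.
#'
#' @param points numeric matrix (or two-column data frame) of (x, y)
#'   coordinates, one point per row; at least 5 non-degenerate points.
#' @return an object of class \code{conic_coefficients}: a named numeric
#'   vector with elements \code{a, b, c, d, e, f}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' fit_ellipse(cbind(cos(th), sin(th)))
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L) {
    stop("`points` must be a two-column numeric matrix of (x, y) coordinates")
  }
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 5L) {
    stop("insufficient points: direct ellipse fitting needs at least 5 points")
  }

  # conditioning: mean-center and scale so RMS radius is sqrt(2)
  mx <- mean(points[, 1L]); my <- mean(points[, 2L])
  xc <- points[, 1L] - mx; yc <- points[, 2L] - my
  s <- sqrt(2) / max(sqrt(mean(xc^2 + yc^2)), .Machine$double.eps)
  x <- xc * s; y <- yc * s

  d1 <- cbind(x^2, x * y, y^2)   # quadratic block
  d2 <- cbind(x, y, 1)           # linear block
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)

  t_mat <- tryCatch(-solve(s3, t(s2)), error = function(e) {
    stop("degenerate fit: points are collinear or coincident")
  })
  # m = C1^{-1} (S1 + S2 T) with C1 the ellipse constraint matrix
  m0 <- s1 + s2 %*% t_mat
  m <- rbind(m0[3L, ] / 2, -m0[2L, ], m0[1L, ] / 2)

  eg <- eigen(m)
  ev <- Re(eg$vectors)
  # select the eigenvector with 4ac - b^2 > 0 (unique for a valid point set)
  cond <- 4 * ev[1L, ] * ev[3L, ] - ev[2L, ]^2
  ok <- which(cond > 1e-12 & abs(Im(eg$values)) < 1e-8 * (1 + abs(Re(eg$values))))
  if (length(ok) == 0L) stop("degenerate fit: no ellipse solution found")
  a1 <- ev[, ok[1L]]
  a2 <- t_mat %*% a1
  co <- c(a1, a2)  # (a, b, c, d, e, f) in the normalized frame

  # undo the normalization x' = s (x - mx), y' = s (y - my)
  qx <- -s * mx; qy <- -s * my
  a <- co[1L] * s^2
  b <- co[2L] * s^2
  c_ <- co[3L] * s^2
  d <- 2 * co[1L] * s * qx + co[2L] * s * qy + co[4L] * s
  e <- co[2L] * s * qx + 2 * co[3L] * s * qy + co[5L] * s
  f <- co[1L] * qx^2 + co[2L] * qx * qy + co[3L] * qy^2 +
    co[4L] * qx + co[5L] * qy + co[6L]

  normalize_conic(c(a = a, b = b, c = c_, d = d, e = e, f = f))
}

# rescale conic coefficients so 4ac - b^2 = 1 exactly, with a > 0
normalize_conic <- function(co) {
  disc <- 4 * co[["a"]] * co[["c"]] - co[["b"]]^2
  if (!is.finite(disc) || disc <= 0) stop("not an ellipse: 4ac - b^2 <= 0")
  co <- co / sqrt(disc)
  if (co[["a"]] < 0) co <- -co
  structure(co, class = "conic_coefficients")
}

#' @export
print.conic_coefficients <- function(x, ...) {
  cat("Conic a x^2 + b x y + c y^2 + d x + e y + f = 0\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Convert conic coefficients to geometric ellipse parameters
#'
#' Solves for the ellipse center from the stationary point of the quadratic
#' form, then obtains semi-axes and orientation from its eigendecomposition.
#'
#' @param conic numeric vector \code{(a, b, c, d, e, f)}, e.g. from
#'   \code{\link{fit_ellipse}}.
#' @return an \code{ellipse_geometry} list with \code{center} (x, y),
#'   \code{semi_major}, \code{semi_minor} (pixels) and \code{orientation}
#'   (radians in (-pi/2, pi/2], angle of the major axis).
#' @export
conic_to_geometry <- function(conic) {
  co <- as.numeric(conic)
  if (length(co) != 6L) stop("conic must have 6 coefficients (a, b, c, d, e, f)")
  a <- co[1L]; b <- co[2L]; c_ <- co[3L]; d <- co[4L]; e <- co[5L]; f <- co[6L]
  disc <- 4 * a * c_ - b^2
  if (!is.finite(disc) || disc <= 0) stop("not an ellipse: b^2 - 4ac >= 0")

  # center: gradient of the quadratic vanishes
  q <- matrix(c(2 * a, b, b, 2 * c_), 2L, 2L)
  center <- drop(solve(q, -c(d, e)))
  # value at the center; must have opposite sign to the (definite) quadratic part
  mu <- a * center[1L]^2 + b * center[1L] * center[2L] + c_ * center[2L]^2 +
    d * center[1L] + e * center[2L] + f
  qf <- matrix(c(a, b / 2, b / 2, c_), 2L, 2L)
  eg <- eigen(qf, symmetric = TRUE)
  ax2 <- -mu / eg$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) stop("not an ellipse: degenerate quadratic form")
  semi <- sqrt(ax2)
  # eigen() returns values in decreasing order; the major axis pairs with the
  # smaller eigenvalue of the quadratic form
  i_major <- which.max(semi)
  v <- eg$vectors[, i_major]
  theta <- atan2(v[2L], v[1L])
  theta <- theta %% pi
  if (theta > pi / 2) theta <- theta - pi
  if (theta <= -pi / 2) theta <- theta + pi

  structure(list(center = center, semi_major = max(semi),
                 semi_minor = min(semi), orientation = theta),
            class = "ellipse_geometry")
}

#' @export
print.ellipse_geometry <- function(x, ...) {
  cat(sprintf("Ellipse: center (%.3f, %.3f), semi-axes (%.3f, %.3f), orientation %.4f rad\n",
              x$center[1L], x$center[2L], x$semi_major, x$semi_minor, x$orientation))
  invisible(x)
}

#' Conic coefficients of a geometric ellipse
#'
#' Inverse of \code{\link{conic_to_geometry}}; mostly useful for constructing
#' test cases and for residual checks.
#'
#' @param geom an \code{ellipse_geometry} (or list with \code{center},
#'   \code{semi_major}, \code{semi_minor}, \code{orientation}).
#' @return \code{conic_coefficients} normalized so \eqn{4ac - b^2 = 1}.
#' @export
geometry_to_conic <- function(geom) {
  ct <- cos(geom$orientation); st <- sin(geom$orientation)
  A2 <- geom$semi_major^2; B2 <- geom$semi_minor^2
  a <- ct^2 / A2 + st^2 / B2
  b <- 2 * ct * st * (1 / A2 - 1 / B2)
  c_ <- st^2 / A2 + ct^2 / B2
  cx <- geom$center[1L]; cy <- geom$center[2L]
  d <- -2 * a * cx - b * cy
  e <- -b * cx - 2 * c_ * cy
  f <- a * cx^2 + b * cx * cy + c_ * cy^2 - 1
  normalize_conic(c(a = a, b = b, c = c_, d = d, e = e, f = f))
}

#' Endpoints of the major axis
#'
#' The major-axis chord of the fitted ellipse is used as the virtual uterine
#' cavity line.
#'
#' @param geom an \code{ellipse_geometry}.
#' @return 2x2 matrix; rows are the two endpoints
#'   \code{center +/- semi_major * (cos(theta), sin(theta))}.
#' @export
major_axis_endpoints <- function(geom) {
  u <- c(cos(geom$orientation), sin(geom$orientation))
  rbind(geom$center - geom$semi_major * u,
        geom$center + geom$semi_major * u)
}

# algebraic residual of points under a conic; used in tests and diagnostics
conic_residual <- function(conic, points) {
  co <- as.numeric(conic)
  x <- points[, 1L]; y <- points[, 2L]
  co[1L] * x^2 + co[2L] * x * y + co[3L] * y^2 + co[4L] * x + co[5L] * y + co[6L]
}
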