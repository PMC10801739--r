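#' Shape-preserving tabulated curves
#'
#' Constitutive curves of the intervertebral disc bushings (moment-angle and
#' force-displacement tables) are interpolated with monotone (Fritsch-Carlson)
#' cubic Hermite splines so that tabulated monotone data can never produce an
#' oscillating, locally negative stiffness. Outside the tabulated range the
#' curve continues linearly with the end slope, which gives a well-defined
#' clamped-slope extrapolation for the stiff ODE solver.
#'
#' @param x,y numeric knots; `x` strictly increasing, `y` non-decreasing.
#' @return An object of class `spinedyn_curve`.
#' @examples
#' cv <- monotone_curve(c(0, 1, 2), c(0, 400, 1000))
#' curve_eval(cv, 1)   # 400, exact at a knot
#' @export
monotone_curve <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2)
  if (any(diff(x) <= 0)) {
    stop("curve abscissae must be strictly increasing", call. = FALSE)
  }
  if (any(diff(y) < 0)) {
    stop("curve ordinates must be monotone non-decreasing", call. = FALSE)
  }
  structure(list(x = x, y = y, m = fritsch_carlson_slopes(x, y)),
            class = "spinedyn_curve")
}

#' Fritsch-Carlson monotone Hermite slopes
#'
#' Mean finite-difference slopes (zero across sign changes), projected
#' back into the Fritsch-Carlson monotonicity region where the Hermite
#' interpolant would otherwise overshoot.
#'
#' @keywords internal
fritsch_carlson_slopes <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  d <- diff(y) / h
  m <- numeric(n)
  m[1] <- d[1]
  m[n] <- d[n - 1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      m[i] <- if (d[i - 1] * d[i] <= 0) 0 else (d[i - 1] + d[i]) / 2
    }
  }
  for (i in seq_len(n - 1)) {
    if (d[i] == 0) {
      m[i] <- 0
      m[i + 1] <- 0
    } else {
      a <- m[i] / d[i]
      b <- m[i + 1] / d[i]
      a2b3 <- 2 * a + b - 3
      ab23 <- a + 2 * b - 3
      if (a2b3 > 0 && ab23 > 0 && a * (a2b3 + ab23) < a2b3^2) {
        tau <- 3 * d[i] / sqrt(a^2 + b^2)
        m[i] <- tau * a
        m[i + 1] <- tau * b
      }
    }
  }
  m
}

#' Evaluate a monotone curve
#'
#' @param curve a [monotone_curve()].
#' @param v numeric vector of abscissae.
#' @return numeric vector; linear continuation with the boundary slope
#'   outside the tabulated range.
#' @export
curve_eval <- function(curve, v) {
  x <- curve$x; y <- curve$y; m <- curve$m
  n <- length(x)
  out <- numeric(length(v))
  below <- v < x[1]
  above <- v > x[n]
  out[below] <- y[1] + m[1] * (v[below] - x[1])
  out[above] <- y[n] + m[n] * (v[above] - x[n])
  mid <- !(below | above)
  if (any(mid)) {
    vm <- v[mid]
    i <- findInterval(vm, x, rightmost.closed = TRUE)
    i[i >= n] <- n - 1
    h <- x[i + 1] - x[i]
    t <- (vm - x[i]) / h
    h00 <- (1 + 2 * t) * (1 - t)^2
    h10 <- t * (1 - t)^2
    h01 <- t^2 * (3 - 2 * t)
    h11 <- t^2 * (t - 1)
    out[mid] <- h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1] + h11 * h * m[i + 1]
  }
  out
}

#' Is a tabulated curve odd-symmetric?
#'
#' Lateral-bending and axial-rotation disc curves must satisfy
#' `f(-x) = -f(x)`; the check requires knots mirrored about zero.
#'
#' @keywords internal
curve_is_odd <- function(curve, tol = 1e-9) {
  x <- curve$x; y <- curve$y
  isTRUE(all.equal(x, -rev(x), tolerance = tol)) &&
    isTRUE(all.equal(y, -rev(y), tolerance = tol))
}
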