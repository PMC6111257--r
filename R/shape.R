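#' Egg shape parameters
#'
#' The two-parameter egg curve \deqn{(X^2+Y^2)^2 = aX^3 + (a-b)XY^2} describes
#' the outline of an egg with rotational symmetry about its major axis.  `a`
#' is the physical length of the major axis; `b` controls elongation and
#' asymmetry.  For a regular chicken egg `b/a` is close to 0.7; `b = 0`
#' degenerates the curve to a circle (a sphere in 3D).
#'
#' @param a Major-axis length (length units, > 0).
#' @param b Second shape parameter (same units, >= 0).
#' @return An object of class `egg_shape` with fields `a` and `b`.
#' @examples
#' sh <- egg_shape(a = 0.06, b = 0.042)
#' is_regular_shape(sh)
#' @export
egg_shape <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            is.finite(a), is.finite(b))
  if (a <= 0) stop("egg shape requires a > 0")
  if (b < 0) stop("egg shape requires b >= 0")
  structure(list(a = a, b = b), class = "egg_shape")
}

#' @export
print.egg_shape <- function(x, ...) {
  cat(sprintf("<egg_shape> a = %g, b = %g (b/a = %.3f%s)\n", x$a, x$b,
              x$b / x$a, if (is_regular_shape(x)) ", regular" else ""))
  invisible(x)
}

#' Is the shape a regular egg?
#'
#' A shape is considered regular when `b/a` lies within 10% of 0.7, i.e. in
#' \[0.63, 0.77\].  The ratio gate is used when deciding whether a
#' shear-compensated fit is physically plausible.
#'
#' @param shape An [egg_shape()].
#' @return Logical scalar.
#' @export
is_regular_shape <- function(shape) {
  r <- shape$b / shape$a
  r >= 0.63 && r <= 0.77
}

#' 2D egg-curve residual
#'
#' Evaluates \eqn{(x^2+y^2)^2 - ax^3 - (a-b)xy^2}; the value is zero exactly
#' when `(x, y)` lies on the 2D egg curve.
#'
#' @param x,y Coordinates (vectorised).
#' @param shape An [egg_shape()].
#' @return Numeric vector of residuals.
#' @export
curve2d_residual <- function(x, y, shape) {
  a <- shape$a; b <- shape$b
  (x^2 + y^2)^2 - a * x^3 - (a - b) * x * y^2
}

#' Squared radius profile along the major axis
#'
#' Solving the egg curve for the squared cross-section radius at axial
#' station `t` gives the quadratic (in \eqn{u = r^2})
#' \deqn{u^2 + (2t^2 - (a-b)t)u + (t^4 - at^3) = 0,}
#' whose larger root is the physical squared radius (the smaller root is
#' negative on the open interval).  The radius vanishes at both terminals
#' `t = 0` and `t = a`.
#'
#' @param t Axial coordinate(s) in `[0, a]`.
#' @param shape An [egg_shape()].
#' @return Squared radius `r^2(t)`, same length as `t`.
#' @export
radius_profile <- function(t, shape) {
  a <- shape$a; b <- shape$b
  if (any(t < -1e-12 * a | t > a * (1 + 1e-12))) {
    stop("axial coordinate t must lie in [0, a]")
  }
  t <- pmin(pmax(t, 0), a)
  B <- 2 * t^2 - (a - b) * t
  C <- t^4 - a * t^3
  disc <- B^2 - 4 * C
  if (any(disc < -1e-12 * a^4)) {
    stop("negative discriminant: invalid egg shape")
  }
  u <- (-B + sqrt(pmax(disc, 0))) / 2
  pmax(u, 0)
}

#' Closed-form egg volume
#'
#' The volume of the solid of revolution of the egg curve,
#' \eqn{V = \pi\int_0^a r^2(t)\,dt}, has the closed form
#' \deqn{V = \frac{\pi}{2}\left(\frac{a^3}{3} - \frac{a^2 b}{3}
#'   + \frac{a b^2}{6} - \frac{b^3}{30}\right),}
#' a function of the shape parameters only -- independent of position,
#' orientation and shear.  At `b = 0` this reduces to the sphere volume
#' \eqn{\pi a^3/6} of diameter `a`.
#'
#' @param shape An [egg_shape()].  Lengths in cm give volume in mL.
#' @return Volume in cubic length units.
#' @export
egg_volume <- function(shape) {
  a <- shape$a; b <- shape$b
  v <- (pi / 2) * (a^3 / 3 - a^2 * b / 3 + a * b^2 / 6 - b^3 / 30)
  if (!is.finite(v)) stop("non-finite volume: invalid egg shape")
  v
}

#' Analytic volume gradient
#'
#' Partial derivatives of [egg_volume()] with respect to `a` and `b`, used in
#' first-order error propagation.
#'
#' @param shape An [egg_shape()].
#' @return Named numeric vector `c(dV_da, dV_db)`.
#' @export
egg_volume_gradient <- function(shape) {
  a <- shape$a; b <- shape$b
  c(dV_da = (pi / 2) * (a^2 - 2 * a * b / 3 + b^2 / 6),
    dV_db = (pi / 2) * (-a^2 / 3 + a * b / 3 - b^2 / 10))
}

#' Standard deviation of the egg volume
#'
#' First-order propagation of the shape-parameter covariance through the
#' closed-form volume:
#' \deqn{\sigma_V = \sqrt{(\partial V/\partial a)^2\sigma_a^2 +
#'   (\partial V/\partial b)^2\sigma_b^2 +
#'   2(\partial V/\partial a)(\partial V/\partial b)\sigma_{ab}}.}
#'
#' @param shape An [egg_shape()].
#' @param var_a,var_b Variances of `a` and `b` (>= 0).
#' @param cov_ab Covariance of `a` and `b`; must satisfy
#'   `|cov_ab| <= sqrt(var_a * var_b)`.
#' @return Standard deviation of the volume (same cubic units as the volume).
#' @export
volume_sigma <- function(shape, var_a, var_b, cov_ab = 0) {
  stopifnot(var_a >= 0, var_b >= 0)
  if (abs(cov_ab) > sqrt(var_a * var_b) * (1 + 1e-9)) {
    stop("invalid covariance: |cov_ab| exceeds sqrt(var_a * var_b)")
  }
  g <- egg_volume_gradient(shape)
  rad <- g[[1]]^2 * var_a + g[[2]]^2 * var_b + 2 * g[[1]] * g[[2]] * cov_ab
  if (rad < -1e-12 * max(var_a, var_b, 1)) stop("negative radicand in volume variance")
  sqrt(max(rad, 0))
}
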