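# Initial-value computation for the egg-model fit, from the raw half-shell
# cloud: top point, in-plane alignment, constrained sphere fit, tip search,
# and orientation from the tip-to-center line.

#' Find the egg top point
#'
#' The shell point nearest the sensor origin (minimum range).  Ties are
#' broken by the lowest point index.
#'
#' @param cloud An [egg_cloud()] or n x 3 matrix.
#' @return The 3-vector of the top point, with its index as attribute
#'   `"index"`.
#' @export
find_top_point <- function(cloud) {
  xyz <- cloud_xyz(cloud)
  if (nrow(xyz) == 0L) stop("empty cloud")
  i <- which.min(rowSums(xyz^2))
  structure(xyz[i, ], index = i)
}

# Rotated-Y extent objective of the in-plane alignment: the width of the
# point set projected on direction (sin theta, cos theta).
y_extent <- function(xy, theta) {
  p <- xy[, 1] * sin(theta) + xy[, 2] * cos(theta)
  max(p) - min(p)
}

#' In-plane alignment angle
#'
#' Finds the rotation angle theta in \[0, 180\] degrees minimizing the
#' rotated-Y extent `max(Y') - min(Y')` of the (translated) 2D point set,
#' which aligns the egg's projected major axis with the X axis.  The width
#' function is piecewise smooth with several local minima, so a fine
#' 0.05-degree scan brackets the global minimum before
#' golden-section/parabolic refinement ([stats::optimize()]) polishes it.
#'
#' @param xy n x 2 matrix of translated 2D coordinates.
#' @return The angle in degrees, in \[0, 180\].
#' @export
optimal_rotation_theta <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L, nrow(xy) >= 2L)
  grid <- seq(0, 180, by = 0.05) * pi / 180
  proj <- xy %*% rbind(sin(grid), cos(grid))
  ext <- apply(proj, 2, function(p) max(p) - min(p))
  k <- which.min(ext)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(function(t) y_extent(xy, t), lower = lo, upper = hi,
                         tol = 1e-6)
  theta <- opt$minimum * 180 / pi
  if (opt$objective > ext[k]) theta <- grid[k] * 180 / pi
  theta <- theta %% 180
  if (theta < 0) theta <- theta + 180
  theta
}

#' Select the horizontal model variant from the alignment angle
#'
#' After the in-plane alignment the major axis is near the X axis.  When
#' the original axis direction is within 45 degrees of X (theta in
#' \[0, 45) or (135, 180\]) Model II (axis about X) is used; otherwise
#' Model I (axis about Y).  The boundaries go with the axis the angle
#' names: 45 -> Model I, 135 -> Model II.
#'
#' @param theta Alignment angle in degrees, in \[0, 180\].
#' @return A [model_variant()] (shear off).
#' @export
select_variant <- function(theta) {
  stopifnot(theta >= 0, theta <= 180)
  model_variant(if (theta < 45 || theta >= 135) "II" else "I",
                with_shear = FALSE)
}

#' Sphere fit with fixed radius
#'
#' Least-squares estimate of the center c minimizing
#' `sum((||p - c|| - r_s)^2)` with the radius held fixed, by Gauss-Newton
#' from the cloud centroid pushed r_s inward (away from the sensor along
#' the mean point direction).  Fixing the radius keeps the fitted sphere
#' at the egg's mid-body rather than ballooning to the major-axis length.
#'
#' @param cloud An [egg_cloud()] or n x 3 matrix (>= 3 points).
#' @param r_s Fixed sphere radius (m, > 0).
#' @return The 3-vector center.
#' @export
fit_sphere_fixed_radius <- function(cloud, r_s) {
  xyz <- cloud_xyz(cloud)
  if (nrow(xyz) < 3L) stop("sphere fit requires at least 3 points")
  stopifnot(r_s > 0)
  ctr <- colMeans(xyz)
  u <- ctr / sqrt(sum(ctr^2))
  c_est <- ctr + r_s * u
  for (it in 1:100) {
    d <- sweep(xyz, 2, c_est)
    nrm <- sqrt(rowSums(d^2))
    f <- nrm - r_s
    J <- -d / nrm
    delta <- tryCatch(solve(crossprod(J), -crossprod(J, f)),
                      error = function(e) stop("degenerate sphere geometry"))
    c_est <- c_est + as.numeric(delta)
    if (sqrt(sum(delta^2)) < 1e-10) return(c_est)
  }
  stop("sphere fit did not converge in 100 iterations")
}

#' Find the egg tip in the aligned cloud
#'
#' Among the points whose distance from the major (X) axis is below the
#' 10th percentile of all axis distances, returns the one farthest from
#' the center.  Ties are broken by the lowest index.
#'
#' @param cloud_aligned n x 3 matrix: cloud re-centered on the sphere
#'   center with the projected major axis rotated onto X.
#' @param center Center in the aligned frame (default the origin).
#' @return The 3-vector tip (aligned frame), with attribute `"index"`.
#' @export
find_tip <- function(cloud_aligned, center = c(0, 0, 0)) {
  xyz <- cloud_xyz(cloud_aligned)
  d <- sweep(xyz, 2, center)
  axis_dist <- sqrt(d[, 2]^2 + d[, 3]^2)
  gate <- axis_dist <= stats::quantile(axis_dist, 0.10)
  cand <- which(gate)
  ctr_dist <- sqrt(rowSums(d[cand, , drop = FALSE]^2))
  i <- cand[which.max(ctr_dist)]
  structure(xyz[i, ], index = i)
}

# Apply / invert the Eq.-style 2D alignment rotation (theta in degrees).
rotate2d <- function(xy, theta_deg) {
  t <- theta_deg * pi / 180
  cbind(cos(t) * xy[, 1] - sin(t) * xy[, 2],
        sin(t) * xy[, 1] + cos(t) * xy[, 2])
}
unrotate2d <- function(xy, theta_deg) rotate2d(xy, -theta_deg)

#' Initial parameter computation
#'
#' Runs the full initialization on a segmented half-shell cloud: top
#' point; in-plane alignment angle and model-variant choice; approximate
#' mid-body radius and the fixed-radius sphere fit for the egg center;
#' re-alignment about the center and the tip search; then the pose from
#' the tip-to-center line by trigonometry, `a0` from the aligned major-axis
#' extent, and `b0 = 0.7 a0`.
#'
#' @param cloud An [egg_cloud()] or n x 3 matrix of eggshell points.
#' @return An object of class `egg_init`: fields `variant`, `pose`,
#'   `shape`, `theta` (degrees), `r_s`, `sphere_center`, `tip`.
#' @export
initial_parameters <- function(cloud) {
  xyz <- cloud_xyz(cloud)
  top <- find_top_point(xyz)
  xy0 <- sweep(xyz[, 1:2, drop = FALSE], 2, top[1:2])
  theta1 <- optimal_rotation_theta(xy0)
  variant <- select_variant(theta1)
  r_s <- y_extent(xy0, theta1 * pi / 180) / 2
  center <- fit_sphere_fixed_radius(xyz, r_s)
  xy_c <- sweep(xyz[, 1:2, drop = FALSE], 2, center[1:2])
  theta2 <- optimal_rotation_theta(xy_c)
  aligned <- cbind(rotate2d(xy_c, theta2), xyz[, 3] - center[3])
  tip_al <- find_tip(aligned)
  tip_xy <- unrotate2d(rbind(tip_al[1:2]), theta2)
  tip <- c(tip_xy[1, ] + center[1:2], tip_al[3] + center[3])
  a0 <- max(aligned[, 1]) - min(aligned[, 1])
  d <- center - tip
  d <- d / sqrt(sum(d^2))
  ang <- axis_angles_from_direction(d, variant)
  pose <- do.call(egg_pose, c(list(xc = tip[1], yc = tip[2], zc = tip[3]), ang))
  structure(list(variant = variant, pose = pose,
                 shape = egg_shape(a0, 0.7 * a0),
                 theta = theta2, r_s = r_s, sphere_center = center,
                 tip = tip),
            class = "egg_init")
}

#' @export
print.egg_init <- function(x, ...) {
  cat(sprintf("<egg_init> Model %s, a0 = %.2f cm, theta = %.1f deg\n",
              x$variant$axis, x$shape$a * 100, x$theta))
  invisible(x)
}

#' Mirror an initial guess to the opposite tip
#'
#' The half-shell silhouette is nearly symmetric, so the tip search may
#' land on either end of the major axis.  This reflects the guessed tip
#' through the sphere center and reverses the axis direction, giving the
#' competing orientation; fitting both and keeping the lower-SSE solution
#' resolves the ambiguity.
#'
#' @param init An `egg_init`.
#' @return The mirrored `egg_init`.
#' @export
flip_initial_guess <- function(init) {
  tip2 <- 2 * init$sphere_center - init$tip
  d <- init$sphere_center - tip2
  d <- d / sqrt(sum(d^2))
  ang <- axis_angles_from_direction(d, init$variant)
  init$pose <- do.call(egg_pose,
                       c(list(xc = tip2[1], yc = tip2[2], zc = tip2[3]), ang))
  init$tip <- tip2
  init
}
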