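# Synthetic range-camera egg scenes with known ground truth.
#
# The generator stands in for the range-camera hardware: it samples the
# implicit egg surface exactly, keeps the half visible from a sensor above
# the egg, resamples onto the sensor's angular pixel grid, optionally
# applies a shear distortion (the exact inverse of the model's back-shear,
# so fitted shear coefficients are directly comparable), and adds isotropic
# Gaussian point noise and per-pixel intensities.

#' Egg shape presets
#'
#' Approximate shapes for common egg types: chicken (a = 6 cm), duck
#' (a = 7 cm) and quail (a = 3 cm), each with the regular ratio b = 0.7a.
#'
#' @param type One of `"chicken"`, `"duck"`, `"quail"`.
#' @return An [egg_shape()] in meters.
#' @export
egg_preset <- function(type = c("chicken", "duck", "quail")) {
  type <- match.arg(type)
  a <- switch(type, chicken = 0.060, duck = 0.070, quail = 0.030)
  egg_shape(a = a, b = 0.7 * a)
}

# Maximum cross-section radius of a shape (m), by dense profile evaluation.
max_radius <- function(shape) {
  t <- seq(0, shape$a, length.out = 512)
  sqrt(max(radius_profile(t, shape)))
}

#' Synthetic scene specification
#'
#' Describes one capture: egg shape and pose, sensor geometry, shear
#' distortion, noise and intensities.  Defaults emulate the recommended
#' capture configuration: sensor-to-egg distance 0.74 m, a 424 x 512
#' angular grid, point noise sigma = 1 mm, a dark stage under a bright egg.
#' If `pose` is `NULL` it is built from `tilt_deg`/`azimuth_deg`: the egg
#' rests under the sensor with its major axis tilted `tilt_deg` out of the
#' sensor's image plane (side-on capture = small tilt; end-on capture,
#' with the sensor 45 degrees over one egg tip, = tilt 45).
#'
#' @param shape An [egg_shape()] (m); default chicken preset.
#' @param pose An [egg_pose()], or `NULL` to derive one.
#' @param variant A [model_variant()], or `NULL` to select from the axis
#'   direction (horizontal models only).
#' @param shear A [shear_params()] distortion applied by the generator.
#' @param tilt_deg Tilt of the major axis out of the sensor image plane.
#' @param azimuth_deg In-plane direction of the major axis (0 = sensor X).
#' @param distance Sensor-to-egg distance in m (nearest shell point).
#' @param rows,cols Pixel grid dimensions.
#' @param pitch Angular pixel pitch in radians.
#' @param noise_sigma Isotropic point-noise standard deviation (m).
#' @param stage_depth Depth of the planar stage (m); default just behind
#'   the egg.
#' @param stage_intensity,egg_intensity Mean intensities (gray levels).
#' @param intensity_sigma Intensity noise standard deviation (gray levels).
#' @param bit_depth Intensity bit depth (8 or 16).
#' @param n_surface Dense surface sample size before grid resampling.
#' @param seed Integer seed fixing all randomness, or `NULL`.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = egg_preset("chicken"), pose = NULL,
                       variant = NULL, shear = shear_params(0, 0),
                       tilt_deg = 10, azimuth_deg = 0,
                       distance = 0.74, rows = 424L, cols = 512L,
                       pitch = 0.0024, noise_sigma = 0.001,
                       stage_depth = NULL,
                       stage_intensity = 30, egg_intensity = 200,
                       intensity_sigma = 0, bit_depth = 8L,
                       n_surface = 20000L, seed = NULL) {
  stopifnot(distance > 0, noise_sigma >= 0, pitch > 0)
  r_max <- max_radius(shape)
  if (is.null(pose)) {
    tilt <- tilt_deg * pi / 180
    az <- azimuth_deg * pi / 180
    d <- c(cos(tilt) * cos(az), cos(tilt) * sin(az), sin(tilt))
    if (is.null(variant)) {
      az_mod <- azimuth_deg %% 180
      variant <- model_variant(
        if (az_mod < 45 || az_mod >= 135) "II" else "I",
        with_shear = FALSE)
    }
    center <- c(0, 0, distance + r_max)
    tip <- center - (shape$a / 2) * d
    ang <- axis_angles_from_direction(d, variant)
    pose_args <- c(list(xc = tip[1], yc = tip[2], zc = tip[3]), ang)
    pose <- do.call(egg_pose, pose_args)
  }
  if (is.null(variant)) variant <- model_variant("II", with_shear = FALSE)
  if (is.null(stage_depth)) stage_depth <- distance + 2 * r_max + 0.01
  structure(list(shape = shape, pose = pose, variant = variant,
                 shear = shear, distance = distance,
                 rows = as.integer(rows), cols = as.integer(cols),
                 pitch = pitch, noise_sigma = noise_sigma,
                 stage_depth = stage_depth,
                 stage_intensity = stage_intensity,
                 egg_intensity = egg_intensity,
                 intensity_sigma = intensity_sigma,
                 bit_depth = as.integer(bit_depth),
                 n_surface = as.integer(n_surface), seed = seed),
            class = "scene_spec")
}

# Sample the full shell exactly in object space.  Returns object-space
# coordinates, outward unit normals, and the axial stations.
sample_surface_object <- function(shape, n) {
  a <- shape$a
  t <- stats::runif(n, 0, a)
  az <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(radius_profile(t, shape))
  q1 <- r * cos(az)
  q2 <- r * sin(az)
  U <- cbind(t, q1, q2)  # axis-first frame; remapped per variant below
  # implicit-surface gradient in the axis-first frame (s, q1, q2)
  s <- t; r2 <- r^2
  dFds <- 4 * s * (s^2 + r2) - 3 * a * s^2 - (a - shape$b) * r2
  dFdr2 <- 2 * (s^2 + r2) - (a - shape$b) * s
  Gn <- cbind(dFds, dFdr2 * 2 * q1, dFdr2 * 2 * q2)
  # orient outward: away from the axis midpoint (the egg is convex)
  mid <- cbind(s - a / 2, q1, q2)
  flip <- rowSums(Gn * mid) < 0
  Gn[flip, ] <- -Gn[flip, ]
  Gn <- Gn / sqrt(rowSums(Gn^2))
  list(U = U, N = Gn, t = t)
}

# Remap axis-first (s, q1, q2) coordinates into the variant's object frame.
axis_first_to_object <- function(M, variant) {
  switch(variant$axis,
         I = cbind(M[, 2], M[, 1], M[, 3]),   # axis along Y
         II = M,                               # axis along X
         III = cbind(M[, 2], M[, 3], M[, 1]))  # axis along Z
}

#' Sample exact points on the full egg shell
#'
#' Draws axial stations and azimuths at random, evaluates the radius
#' profile, and maps the resulting exact surface points to sensor space
#' through the inverse pose transform.  Every output point satisfies the
#' implicit model equation to machine precision.
#'
#' @param shape An [egg_shape()].
#' @param pose An [egg_pose()].
#' @param variant A [model_variant()].
#' @param n Number of points.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param shear Optional [shear_params()]: forward shear distortion applied
#'   in object space (the inverse of the model's back-shear).
#' @return An [egg_cloud()] of n sensor-space points.
#' @export
sample_surface <- function(shape, pose, variant, n, seed = NULL, shear = NULL) {
  run <- function() {
    smp <- sample_surface_object(shape, n)
    U <- axis_first_to_object(smp$U, variant)
    if (!is.null(shear)) {
      U[, 1] <- U[, 1] + shear$sh_x * U[, 3]
      U[, 2] <- U[, 2] + shear$sh_y * U[, 3]
    }
    egg_cloud(object_to_sensor(U, pose, variant))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Render the visible half shell on the sensor grid
#'
#' Emulates a single range-camera capture of the egg: exact surface points
#' are filtered to the half visible from the sensor (outward normal facing
#' the sensor; exact for a convex body), resampled to one point per angular
#' pixel (nearest along each ray), distorted by the forward shear, and
#' perturbed by isotropic Gaussian noise.  Per-point intensities emulate a
#' bright shell.
#'
#' @param spec A [scene_spec()].
#' @return A list with `cloud` (an [egg_cloud()] with intensity and grid
#'   indices) and `truth` (shape, pose, shear, variant, visible fraction).
#' @export
render_half_shell <- function(spec) {
  run <- function() render_half_shell_impl(spec)
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}

render_half_shell_impl <- function(spec) {
  smp <- sample_surface_object(spec$shape, spec$n_surface)
  U <- axis_first_to_object(smp$U, spec$variant)
  N_obj <- axis_first_to_object(smp$N, spec$variant)
  # forward shear distortion (inverse of the model's back-shear)
  U[, 1] <- U[, 1] + spec$shear$sh_x * U[, 3]
  U[, 2] <- U[, 2] + spec$shear$sh_y * U[, 3]
  P <- object_to_sensor(U, spec$pose, spec$variant)
  R <- pose_rotation(spec$pose, spec$variant)
  N_sens <- N_obj %*% R  # rows: R^T n
  visible <- rowSums(N_sens * P) < 0  # sensor at the origin
  n_vis <- sum(visible)
  P <- P[visible, , drop = FALSE]
  # angular grid resampling: keep the nearest point in each pixel cell
  cell <- grid_cell(P, spec)
  rng <- sqrt(rowSums(P^2))
  key <- paste(cell$row, cell$col)
  ord <- order(rng)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  P <- P[keep, , drop = FALSE]
  grid <- cbind(row = cell$row[keep], col = cell$col[keep])
  if (spec$noise_sigma > 0) {
    P <- P + matrix(stats::rnorm(length(P), 0, spec$noise_sigma), ncol = 3)
  }
  intens <- quantize_intensity(
    spec$egg_intensity + stats::rnorm(nrow(P), 0, spec$intensity_sigma),
    spec$bit_depth)
  list(cloud = egg_cloud(P, intensity = intens, grid = grid),
       truth = list(shape = spec$shape, pose = spec$pose,
                    shear = spec$shear, variant = spec$variant,
                    visible_fraction = n_vis / spec$n_surface,
                    n_points = nrow(P)))
}

grid_cell <- function(P, spec) {
  list(row = as.integer(round(atan2(P[, 2], P[, 3]) / spec$pitch +
                                (spec$rows + 1) / 2)),
       col = as.integer(round(atan2(P[, 1], P[, 3]) / spec$pitch +
                                (spec$cols + 1) / 2)))
}

quantize_intensity <- function(v, bit_depth) {
  top <- 2^bit_depth - 1
  pmin(pmax(round(v), 0), top)
}

#' Render a full scene: stage plane plus egg
#'
#' Rasterizes a dark planar stage and the bright visible half shell onto
#' the sensor's pixel grid, with per-pixel ground-truth labels.  The result
#' feeds the segmentation module end to end.
#'
#' @param spec A [scene_spec()].
#' @return A `range_frame`: matrices `x`, `y`, `z`, `intensity`, logical
#'   `valid`, character `label` (`"stage"`/`"egg"`), plus the truth record.
#' @export
render_scene <- function(spec) {
  run <- function() render_scene_impl(spec)
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}

render_scene_impl <- function(spec) {
  rows <- spec$rows; cols <- spec$cols
  au <- (seq_len(cols) - (cols + 1) / 2) * spec$pitch
  av <- (seq_len(rows) - (rows + 1) / 2) * spec$pitch
  z <- matrix(spec$stage_depth, rows, cols)
  x <- z * matrix(tan(au), rows, cols, byrow = TRUE)
  y <- z * matrix(tan(av), rows, cols)
  if (spec$noise_sigma > 0) {
    x <- x + matrix(stats::rnorm(rows * cols, 0, spec$noise_sigma), rows, cols)
    y <- y + matrix(stats::rnorm(rows * cols, 0, spec$noise_sigma), rows, cols)
    z <- z + matrix(stats::rnorm(rows * cols, 0, spec$noise_sigma), rows, cols)
  }
  intensity <- matrix(quantize_intensity(
    spec$stage_intensity + stats::rnorm(rows * cols, 0, spec$intensity_sigma),
    spec$bit_depth), rows, cols)
  label <- matrix("stage", rows, cols)
  hs <- render_half_shell_impl(spec)
  g <- hs$cloud$grid
  inside <- g[, 1] >= 1 & g[, 1] <= rows & g[, 2] >= 1 & g[, 2] <= cols
  idx <- cbind(g[inside, 1], g[inside, 2])
  x[idx] <- hs$cloud$xyz[inside, 1]
  y[idx] <- hs$cloud$xyz[inside, 2]
  z[idx] <- hs$cloud$xyz[inside, 3]
  intensity[idx] <- hs$cloud$intensity[inside]
  label[idx] <- "egg"
  structure(list(x = x, y = y, z = z, intensity = intensity,
                 valid = matrix(TRUE, rows, cols), label = label,
                 pitch = spec$pitch, rows = rows, cols = cols,
                 truth = hs$truth),
            class = "range_frame")
}

#' @export
print.range_frame <- function(x, ...) {
  cat(sprintf("<range_frame> %d x %d, %d valid points (%d egg-labelled)\n",
              x$rows, x$cols, sum(x$valid), sum(x$label == "egg" & x$valid)))
  invisible(x)
}

#' Flatten a range frame to a point cloud
#'
#' @param frame A `range_frame`.
#' @return An [egg_cloud()] with intensities and grid indices; the
#'   per-pixel labels are attached as attribute `"label"`.
#' @export
frame_to_cloud <- function(frame) {
  ok <- which(frame$valid)
  rc <- arrayInd(ok, c(frame$rows, frame$cols))
  cl <- egg_cloud(cbind(frame$x[ok], frame$y[ok], frame$z[ok]),
                  intensity = as.numeric(frame$intensity[ok]),
                  grid = rc)
  attr(cl, "label") <- frame$label[ok]
  cl
}
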