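#' Egg pose: tip position and orientation
#'
#' The pose places the egg model in sensor space: `(xc, yc, zc)` is the
#' position of the egg tip (the object-space origin) in meters, and the
#' angles rotate sensor-space offsets into object space.  Each model variant
#' uses exactly two of the three angles (Model I: Omega about X and Psi
#' about Z; Model II: Phi about Y and Psi about Z; Model III: Omega and Phi);
#' the unused angle is held at 0.
#'
#' @param xc,yc,zc Tip coordinates in sensor space (m).
#' @param omega,psi,phi Rotation angles about the X, Z and Y axes (radians).
#' @return An object of class `egg_pose`.
#' @export
egg_pose <- function(xc = 0, yc = 0, zc = 0, omega = 0, psi = 0, phi = 0) {
  stopifnot(is.finite(c(xc, yc, zc, omega, psi, phi)))
  structure(list(xc = xc, yc = yc, zc = zc,
                 omega = omega, psi = psi, phi = phi),
            class = "egg_pose")
}

#' @export
print.egg_pose <- function(x, ...) {
  cat(sprintf("<egg_pose> tip = (%.4f, %.4f, %.4f) m, Omega = %.2f deg, Psi = %.2f deg, Phi = %.2f deg\n",
              x$xc, x$yc, x$zc,
              x$omega * 180 / pi, x$psi * 180 / pi, x$phi * 180 / pi))
  invisible(x)
}

#' Shear-distortion parameters
#'
#' Back-shear coefficients absorbing shear-like range-camera distortion:
#' `X' = X - sh_x * Z`, `Y' = Y - sh_y * Z` in object space.  `(0, 0)`
#' reduces every sheared model to its shear-free form.
#'
#' @param sh_x,sh_y Dimensionless shear coefficients.
#' @return An object of class `shear_params`.
#' @export
shear_params <- function(sh_x = 0, sh_y = 0) {
  stopifnot(is.finite(c(sh_x, sh_y)))
  structure(list(sh_x = sh_x, sh_y = sh_y), class = "shear_params")
}

#' Model variant
#'
#' Selects which axis the egg's major axis is closest to: Model I (axis near
#' the sensor Y axis, horizontal), Model II (axis near X, horizontal) or
#' Model III (axis near Z, vertical).  Shear compensation is defined only for
#' the two horizontal models.
#'
#' @param axis One of `"I"`, `"II"`, `"III"`.
#' @param with_shear Logical; include the two shear parameters.
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(axis = c("II", "I", "III"), with_shear = FALSE) {
  axis <- match.arg(axis)
  if (with_shear && axis == "III") {
    stop("shear parameters are not defined for the vertical model (III)")
  }
  structure(list(axis = axis, with_shear = with_shear), class = "model_variant")
}

# Right-handed elementary rotations: positive angle = counter-clockwise
# looking down the named axis toward the origin.
rot_x <- function(t) {
  c_ <- cos(t); s_ <- sin(t)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}
rot_y <- function(t) {
  c_ <- cos(t); s_ <- sin(t)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
rot_z <- function(t) {
  c_ <- cos(t); s_ <- sin(t)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}
drot_x <- function(t) {
  c_ <- cos(t); s_ <- sin(t)
  matrix(c(0, 0, 0, 0, -s_, c_, 0, -c_, -s_), 3, 3)
}
drot_y <- function(t) {
  c_ <- cos(t); s_ <- sin(t)
  matrix(c(-s_, 0, -c_, 0, 0, 0, c_, 0, -s_), 3, 3)
}
drot_z <- function(t) {
  c_ <- cos(t); s_ <- sin(t)
  matrix(c(-s_, c_, 0, -c_, -s_, 0, 0, 0, 0), 3, 3)
}

# Combined rotation for a variant, in the model's printed matrix order:
# I: R3(Psi) R1(Omega); II: R3(Psi) R2(Phi); III: R2(Phi) R1(Omega).
pose_rotation <- function(pose, variant) {
  switch(variant$axis,
         I = rot_z(pose$psi) %*% rot_x(pose$omega),
         II = rot_z(pose$psi) %*% rot_y(pose$phi),
         III = rot_y(pose$phi) %*% rot_x(pose$omega))
}

# Derivatives of the combined rotation with respect to the two active
# angles, returned as a named list in parameter order (first angle, second).
pose_rotation_derivs <- function(pose, variant) {
  switch(variant$axis,
         I = list(omega = rot_z(pose$psi) %*% drot_x(pose$omega),
                  psi   = drot_z(pose$psi) %*% rot_x(pose$omega)),
         II = list(phi = rot_z(pose$psi) %*% drot_y(pose$phi),
                   psi = drot_z(pose$psi) %*% rot_y(pose$phi)),
         III = list(omega = rot_y(pose$phi) %*% drot_x(pose$omega),
                    phi   = drot_y(pose$phi) %*% rot_x(pose$omega)))
}

# Names of the two active angles for a variant, in parameter-vector order.
variant_angles <- function(variant) {
  switch(variant$axis,
         I = c("omega", "psi"),
         II = c("phi", "psi"),
         III = c("omega", "phi"))
}

# The object-space unit vector along which the egg's major axis lies.
variant_axis_vector <- function(variant) {
  switch(variant$axis,
         I = c(0, 1, 0),
         II = c(1, 0, 0),
         III = c(0, 0, 1))
}

#' Transform sensor-space points to object space
#'
#' Applies the model transform `u = R [p - c]`: translation by the negative
#' tip position followed by the variant's two elementary rotations in the
#' model's matrix order (I: `R3(Psi) R1(Omega)`; II: `R3(Psi) R2(Phi)`;
#' III: `R2(Phi) R1(Omega)`).
#'
#' @param points n x 3 matrix of sensor-space coordinates (m).
#' @param pose An [egg_pose()].
#' @param variant A [model_variant()].
#' @return n x 3 matrix of object-space coordinates.
#' @export
sensor_to_object <- function(points, pose, variant) {
  points <- cloud_xyz(points)
  if (nrow(points) == 0L) stop("empty point set")
  R <- pose_rotation(pose, variant)
  d <- sweep(points, 2, c(pose$xc, pose$yc, pose$zc))
  d %*% t(R)
}

#' Inverse transform: object space back to sensor space
#'
#' Exact inverse of [sensor_to_object()] by orthogonality of the rotations.
#'
#' @inheritParams sensor_to_object
#' @param points n x 3 matrix of object-space coordinates.
#' @return n x 3 matrix of sensor-space coordinates.
#' @export
object_to_sensor <- function(points, pose, variant) {
  points <- cloud_xyz(points)
  R <- pose_rotation(pose, variant)
  sweep(points %*% R, 2, c(pose$xc, pose$yc, pose$zc), `+`)
}

#' Back-shear object-space coordinates
#'
#' `X' = X - sh_x * Z`, `Y' = Y - sh_y * Z`; `Z` is unchanged.
#'
#' @param x,y,z Object-space coordinates (vectorised).
#' @param shear A [shear_params()].
#' @return List with components `x` and `y` (the sheared coordinates).
#' @export
back_shear <- function(x, y, z, shear) {
  list(x = x - shear$sh_x * z, y = y - shear$sh_y * z)
}

# Pose angles that map the sensor-space axis direction d (unit vector, tip
# toward blunt end) onto the variant's object-space axis.  Derived from
# d = R^T e_axis for each variant's rotation order.
axis_angles_from_direction <- function(d, variant) {
  d <- d / sqrt(sum(d^2))
  switch(variant$axis,
         I = list(psi = asin(max(-1, min(1, d[1]))),
                  omega = atan2(-d[3], d[2])),
         II = list(psi = asin(max(-1, min(1, -d[2]))),
                   phi = atan2(d[3], d[1])),
         III = list(phi = asin(max(-1, min(1, -d[1]))),
                    omega = atan2(d[2], d[3])))
}

# Sensor-space unit direction of the egg's major axis implied by a pose.
axis_direction_from_pose <- function(pose, variant) {
  R <- pose_rotation(pose, variant)
  as.numeric(t(R) %*% variant_axis_vector(variant))
}
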