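# Implicit 3D egg models and their analytic derivatives.
#
# All three variants share the quartic condition
#   F = (s^2 + r^2)^2 - a s^3 - (a - b) s r^2
# where s is the object-space coordinate along the major axis and r^2 the
# squared distance from it.  Variant I: s = Y, r^2 = X^2 + Z^2;
# variant II: s = X, r^2 = Y^2 + Z^2; variant III: s = Z, r^2 = X^2 + Y^2.
# With shear compensation the back-sheared X' and Y' replace X and Y
# everywhere they appear (horizontal models only); Z is untouched.

# Core evaluation shared by the residual and the Jacobians.  Returns the
# residual F together with the building blocks needed for derivatives.
model_eval <- function(points, shape, pose, shear, variant) {
  P <- cloud_xyz(points)
  a <- shape$a; b <- shape$b
  if (is.null(shear)) shear <- shear_params(0, 0)
  if (variant$axis == "III" && (shear$sh_x != 0 || shear$sh_y != 0)) {
    stop("shear parameters are not defined for the vertical model (III)")
  }
  R <- pose_rotation(pose, variant)
  D <- sweep(P, 2, c(pose$xc, pose$yc, pose$zc))
  U <- D %*% t(R)
  X <- U[, 1]; Y <- U[, 2]; Z <- U[, 3]
  shx <- shear$sh_x; shy <- shear$sh_y
  Xp <- X - shx * Z
  Yp <- Y - shy * Z
  if (variant$axis == "I") {
    s <- Yp; r2 <- Xp^2 + Z^2
  } else if (variant$axis == "II") {
    s <- Xp; r2 <- Yp^2 + Z^2
  } else {
    s <- Z; r2 <- X^2 + Y^2
  }
  F <- (s^2 + r2)^2 - a * s^3 - (a - b) * s * r2
  list(P = P, R = R, D = D, X = X, Y = Y, Z = Z, Xp = Xp, Yp = Yp,
       s = s, r2 = r2, F = F, a = a, b = b, shx = shx, shy = shy)
}

#' Implicit model residual
#'
#' Transforms sensor-space points to object space, applies the back-shear
#' when requested, and evaluates the implicit egg-surface condition.  The
#' residual is zero exactly when the point lies on the model surface.
#'
#' @param points n x 3 matrix or [egg_cloud()] of sensor-space points.
#' @param shape An [egg_shape()].
#' @param pose An [egg_pose()].
#' @param variant A [model_variant()].
#' @param shear A [shear_params()] or `NULL` for the shear-free model.
#' @return Numeric vector of residuals (length n).
#' @export
model_residual <- function(points, shape, pose, variant, shear = NULL) {
  model_eval(points, shape, pose, shear, variant)$F
}

# Parameter vector layout for a variant: two angles, tip position, shape,
# and optionally the two shear coefficients.
param_names <- function(variant) {
  nm <- c(variant_angles(variant), "xc", "yc", "zc", "a", "b")
  if (variant$with_shear) nm <- c(nm, "sh_x", "sh_y")
  nm
}

params_pack <- function(shape, pose, shear, variant) {
  ang <- variant_angles(variant)
  th <- c(pose[[ang[1]]], pose[[ang[2]]],
          pose$xc, pose$yc, pose$zc, shape$a, shape$b)
  if (variant$with_shear) th <- c(th, shear$sh_x, shear$sh_y)
  stats::setNames(th, param_names(variant))
}

params_unpack <- function(theta, variant) {
  ang <- variant_angles(variant)
  pose_args <- list(xc = theta[["xc"]], yc = theta[["yc"]], zc = theta[["zc"]])
  pose_args[[ang[1]]] <- theta[[1]]
  pose_args[[ang[2]]] <- theta[[2]]
  list(shape = egg_shape(theta[["a"]], theta[["b"]]),
       pose = do.call(egg_pose, pose_args),
       shear = if (variant$with_shear) {
         shear_params(theta[["sh_x"]], theta[["sh_y"]])
       } else {
         shear_params(0, 0)
       })
}

# Analytic Jacobians of the condition equations.  Returns the residual F,
# A (n x u partials w.r.t. the parameter vector) and B (n x 3 partials
# w.r.t. each point's own (x, y, z); the full observation Jacobian is
# block-diagonal with these rows).
model_jacobians <- function(points, shape, pose, shear, variant) {
  ev <- model_eval(points, shape, pose, shear, variant)
  a <- ev$a; b <- ev$b
  s <- ev$s; r2 <- ev$r2; Z <- ev$Z
  dFds <- 4 * s * (s^2 + r2) - 3 * a * s^2 - (a - b) * r2
  dFdr2 <- 2 * (s^2 + r2) - (a - b) * s
  if (variant$axis == "I") {
    dFdXp <- dFdr2 * 2 * ev$Xp
    dFdYp <- dFds
    gZ <- dFdr2 * 2 * Z - ev$shx * dFdXp - ev$shy * dFdYp
    G <- cbind(dFdXp, dFdYp, gZ)
  } else if (variant$axis == "II") {
    dFdXp <- dFds
    dFdYp <- dFdr2 * 2 * ev$Yp
    gZ <- dFdr2 * 2 * Z - ev$shx * dFdXp - ev$shy * dFdYp
    G <- cbind(dFdXp, dFdYp, gZ)
  } else {
    dFdXp <- NULL; dFdYp <- NULL
    G <- cbind(dFdr2 * 2 * ev$X, dFdr2 * 2 * ev$Y, dFds)
  }
  B <- G %*% ev$R
  dR <- pose_rotation_derivs(pose, variant)
  ang <- variant_angles(variant)
  A_ang <- vapply(ang, function(nm) {
    dU <- ev$D %*% t(dR[[nm]])
    rowSums(G * dU)
  }, numeric(nrow(B)))
  A <- cbind(A_ang, -B, -s^3 - s * r2, s * r2)
  if (variant$with_shear) {
    A <- cbind(A, dFdXp * (-Z), dFdYp * (-Z))
  }
  colnames(A) <- param_names(variant)
  if (any(!is.finite(A)) || any(!is.finite(B))) {
    stop("non-finite partial derivatives: degenerate parameters")
  }
  list(F = ev$F, A = A, B = B)
}
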