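# Gauss-Helmert least-squares estimation of egg shape, pose and optional
# shear from an implicit condition equation per point:
#   A delta + B v + w = 0,  Q = sigma_obs^2 I.
# B is block-diagonal with one 1 x 3 block per point, so B Q B^T is diagonal
# and the normal equations are formed with per-point weights.

#' Fit options
#'
#' @param max_iter Maximum Gauss-Helmert iterations.
#' @param tol_len Convergence tolerance on length corrections (m): tip
#'   position and shape parameters.
#' @param tol_ang Convergence tolerance on angle (rad) and shear
#'   (dimensionless) corrections.
#' @param sigma_obs A-priori standard deviation of each point coordinate
#'   (m); the range camera's point precision, 1 mm by default.
#' @param use_shear Estimate the two shear-distortion coefficients.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(max_iter = 50L, tol_len = 1e-9, tol_ang = 1e-8,
                        sigma_obs = 0.001, use_shear = FALSE) {
  stopifnot(max_iter >= 1L, sigma_obs > 0, tol_len > 0, tol_ang > 0)
  structure(list(max_iter = as.integer(max_iter), tol_len = tol_len,
                 tol_ang = tol_ang, sigma_obs = sigma_obs,
                 use_shear = use_shear), class = "fit_options")
}

# Per-parameter convergence tolerances in parameter-vector order.
param_tol <- function(variant, options) {
  nm <- param_names(variant)
  tol <- ifelse(nm %in% c("xc", "yc", "zc", "a", "b"),
                options$tol_len, options$tol_ang)
  stats::setNames(tol, nm)
}

#' Linearize the egg model at the current estimates
#'
#' Evaluates the condition equations and their analytic partial
#' derivatives: `A` (n x u, with respect to the parameters) and the
#' per-point 1 x 3 blocks of `B` (with respect to each observed point),
#' plus the misclosure `w` evaluated at the adjusted observations.
#'
#' @param cloud Observed points (n x 3 matrix or [egg_cloud()]).
#' @param shape,pose,shear,variant Current estimates.
#' @param adjusted Adjusted observations (defaults to the observed points).
#' @return List with `A` (n x u), `B` (n x 3 row blocks) and `w` (length n).
#' @export
ghm_linearize <- function(cloud, shape, pose, shear, variant,
                          adjusted = NULL) {
  l_obs <- cloud_xyz(cloud)
  if (is.null(adjusted)) adjusted <- l_obs
  jac <- model_jacobians(adjusted, shape, pose, shear, variant)
  v0 <- adjusted - l_obs
  list(A = jac$A, B = jac$B, w = jac$F - rowSums(jac$B * v0))
}

new_egg_fit <- function(variant, shape, pose, shear, cov, sse, dof,
                        sigma0_sq, converged, iterations, n,
                        sse_history = numeric(), note = NA_character_) {
  structure(list(variant = variant, shape = shape, pose = pose,
                 shear = shear, cov = cov, sse = sse, dof = dof,
                 sigma0_sq = sigma0_sq, converged = converged,
                 iterations = iterations, n = n,
                 sse_history = sse_history, note = note),
            class = "egg_fit")
}

#' Fit the egg model by Gauss-Helmert least squares
#'
#' Iterates the Gauss-Helmert solution of the implicit egg model: at each
#' pass the condition equations are linearized at the current parameters
#' and adjusted observations, the parameter corrections solved from the
#' weighted normal equations, and the observation residuals recovered
#' through the Lagrange multipliers.  Iteration stops when every
#' correction falls below its tolerance (lengths and angles separately) or
#' at the iteration cap.  Non-convergence -- including a singular normal
#' matrix from degenerate capture geometry, e.g. too few points along the
#' major axis -- is reported in the result, never raised, so batch runs
#' can tabulate "no solution" cases.
#'
#' The parameter covariance is the a-posteriori-scaled inverse normal
#' matrix, `sigma0_hat^2 (A' (BQB')^-1 A)^-1` with
#' `sigma0_hat^2 = v' Q^-1 v / (n - u)`.
#'
#' @param cloud Observed eggshell points (n x 3 matrix or [egg_cloud()]).
#' @param init An `egg_init` from [initial_parameters()] (or a compatible
#'   list with `variant`, `pose`, `shape`).
#' @param options A [fit_options()].
#' @return An object of class `egg_fit`.
#' @export
fit_egg <- function(cloud, init, options = fit_options()) {
  l_obs <- cloud_xyz(cloud)
  n <- nrow(l_obs)
  variant <- model_variant(init$variant$axis, with_shear = options$use_shear)
  u <- length(param_names(variant))
  if (n <= u) stop(sprintf("need more than %d points to estimate %d parameters", u, u))
  theta <- params_pack(init$shape, init$pose, shear_params(0, 0), variant)
  tol <- param_tol(variant, options)
  sigma2 <- options$sigma_obs^2
  l_adj <- l_obs
  sse_history <- numeric(0)
  converged <- FALSE
  note <- NA_character_
  iterations <- 0L
  N <- NULL
  fail <- function(msg) {
    new_egg_fit(variant, tryCatch(params_unpack(theta, variant)$shape,
                                  error = function(e) init$shape),
                init$pose, NULL, NULL, NA_real_, n - u, NA_real_,
                FALSE, iterations, n, sse_history, msg)
  }
  # orthogonal-distance merit: each point is Newton-projected onto the
  # implicit surface and the weighted squared distances summed.  This is
  # the Gauss-Helmert objective v' Q^-1 v itself (Q isotropic), evaluated
  # without linearization error, and is used only for step control.
  merit <- function(th) {
    est <- params_unpack(th, variant)
    Q <- l_obs
    for (k in 1:12) {
      jac <- model_jacobians(Q, est$shape, est$pose, est$shear, variant)
      g2 <- pmax(rowSums(jac$B^2), 1e-30)
      Q <- Q - jac$B * (jac$F / g2)
    }
    sum((Q - l_obs)^2) / sigma2
  }
  m_cur <- tryCatch(merit(theta), error = function(e) Inf)
  lm_damp <- 0  # Levenberg-Marquardt damping, raised only when a step fails
  for (it in seq_len(options$max_iter)) {
    iterations <- it
    est <- tryCatch(params_unpack(theta, variant), error = function(e) e)
    if (inherits(est, "error")) return(fail(conditionMessage(est)))
    lin <- tryCatch(
      ghm_linearize(l_obs, est$shape, est$pose, est$shear, variant, l_adj),
      error = function(e) e)
    if (inherits(lin, "error")) return(fail(conditionMessage(lin)))
    M <- sigma2 * rowSums(lin$B^2)
    # a point at the model's tip singularity has a vanishing gradient and
    # carries no linearized information: exclude it from this pass
    ok <- M > 1e-10 * max(M)
    if (sum(ok) <= u) return(fail("degenerate observation geometry"))
    Aw <- lin$A[ok, , drop = FALSE] / M[ok]
    N <- crossprod(lin$A[ok, , drop = FALSE], Aw)
    rhs <- crossprod(Aw, lin$w[ok])
    dN <- diag(N)
    if (any(dN <= 0) || any(!is.finite(dN))) {
      return(fail("singular normal matrix (ill-posed geometry)"))
    }
    # damped Gauss-Helmert step; raise the damping until the
    # gradient-weighted merit decreases, then relax it again
    accepted <- FALSE
    for (try in 1:15) {
      Nd <- N + lm_damp * diag(dN, nrow = u)
      delta <- tryCatch(as.numeric(-solve(Nd, rhs)), error = function(e) NULL)
      if (!is.null(delta)) {
        m_try <- tryCatch(merit(theta + delta), error = function(e) Inf)
        if (m_try <= m_cur * (1 + 1e-12)) { accepted <- TRUE; break }
      }
      lm_damp <- if (lm_damp == 0) 1e-4 else lm_damp * 10
    }
    if (!accepted) {
      converged <- all(abs(delta) < tol)
      if (!converged) note <- "stalled: no descent step found"
      break
    }
    lm_damp <- lm_damp / 10
    if (lm_damp < 1e-12) lm_damp <- 0
    lambda <- numeric(n)
    lambda[ok] <- -(as.numeric(lin$A[ok, , drop = FALSE] %*% delta) + lin$w[ok]) / M[ok]
    v <- lin$B * (sigma2 * lambda)
    theta <- theta + delta
    l_adj <- l_obs + v
    m_cur <- m_try
    sse_history <- c(sse_history, m_try)
    if (all(abs(delta) < tol)) { converged <- TRUE; break }
  }
  est <- tryCatch(params_unpack(theta, variant), error = function(e) e)
  if (inherits(est, "error")) return(fail(conditionMessage(est)))
  lin <- tryCatch(
    ghm_linearize(l_obs, est$shape, est$pose, est$shear, variant, l_adj),
    error = function(e) e)
  if (inherits(lin, "error")) return(fail(conditionMessage(lin)))
  v <- l_adj - l_obs
  sse <- sum(v^2) / sigma2
  dof <- n - u
  sigma0_sq <- sse / dof
  M <- sigma2 * rowSums(lin$B^2)
  ok <- M > 1e-10 * max(M)
  N <- crossprod(lin$A[ok, , drop = FALSE], lin$A[ok, , drop = FALSE] / M[ok])
  cov <- tryCatch(sigma0_sq * solve(N), error = function(e) NULL)
  if (!is.null(cov)) dimnames(cov) <- list(param_names(variant), param_names(variant))
  new_egg_fit(variant, est$shape, est$pose,
              if (options$use_shear) est$shear else NULL,
              cov, sse, dof, sigma0_sq, converged, iterations, n,
              sse_history,
              if (converged) NA_character_ else
                if (!is.na(note)) note else "iteration cap reached")
}

#' @export
print.egg_fit <- function(x, ...) {
  cat(sprintf("<egg_fit> Model %s%s, %d points, %d iterations, %s\n",
              x$variant$axis, if (x$variant$with_shear) " + shear" else "",
              x$n, x$iterations,
              if (x$converged) "converged" else paste0("NOT converged (", x$note, ")")))
  if (x$converged) {
    cat(sprintf("  a = %.2f cm, b = %.2f cm (b/a = %.3f), SSE = %.3g, dof = %d\n",
                x$shape$a * 100, x$shape$b * 100, x$shape$b / x$shape$a,
                x$sse, x$dof))
    if (!is.null(x$volume)) {
      cat(sprintf("  V = %.2f +/- %.2f mL\n",
                  x$volume$V * 1e6, x$volume$sigma_V * 1e6))
    }
  }
  invisible(x)
}

#' Choose between the plain and the shear-compensated fit
#'
#' The shear-compensated fit is kept only when it converged, reduced the
#' (weighted) sum of squared residuals, and produced a realistic egg shape
#' (b/a within 10% of 0.7).  Otherwise the plain fit is returned.  Both
#' SSEs and the decision are recorded in the result's `selection` field.
#'
#' @param fit_plain,fit_shear `egg_fit` results on the same cloud.
#' @return The selected `egg_fit`.
#' @export
select_shear_model <- function(fit_plain, fit_shear) {
  if (!fit_plain$converged && !fit_shear$converged) {
    stop("neither the plain nor the shear fit converged")
  }
  take_shear <- fit_shear$converged &&
    fit_plain$converged && fit_shear$sse < fit_plain$sse &&
    is_regular_shape(fit_shear$shape)
  if (!fit_plain$converged && fit_shear$converged) {
    take_shear <- is_regular_shape(fit_shear$shape)
  }
  sel <- if (take_shear) fit_shear else fit_plain
  sel$selection <- list(chosen = if (take_shear) "shear" else "plain",
                        sse_plain = fit_plain$sse, sse_shear = fit_shear$sse,
                        ratio_shear = fit_shear$shape$b / fit_shear$shape$a,
                        shear_converged = fit_shear$converged)
  sel
}

# Fit with both tip orientations of the initial guess and keep the better
# (converged with lower SSE) result.
fit_egg_both_ends <- function(cloud, init, options) {
  f1 <- fit_egg(cloud, init, options)
  f2 <- fit_egg(cloud, flip_initial_guess(init), options)
  if (f1$converged && f2$converged) {
    if (f1$sse <= f2$sse) f1 else f2
  } else if (f1$converged) {
    f1
  } else if (f2$converged) {
    f2
  } else {
    f1
  }
}

#' Estimate an egg's volume from a half-shell point cloud
#'
#' End-to-end estimation: initial values from the cloud, Gauss-Helmert fit
#' (both tip orientations of the initial guess are tried and the lower-SSE
#' converged solution kept), optional shear compensation with the
#' SSE/shape-ratio selection rule, then the closed-form volume and its
#' standard deviation from the shape estimates and their covariance.
#'
#' @param cloud Eggshell points (n x 3 matrix or [egg_cloud()], meters).
#' @param options A [fit_options()]; its `use_shear` field is ignored in
#'   favour of `shear`.
#' @param shear `"auto"` (fit both, apply the selection rule), `"on"` or
#'   `"off"`.
#' @return An `egg_fit` with a `volume` field (`V`, `sigma_V` in cubic
#'   meters; multiply by 1e6 for mL) when converged.
#' @export
estimate_egg_volume <- function(cloud, options = fit_options(),
                                shear = c("auto", "on", "off")) {
  shear <- match.arg(shear)
  init <- initial_parameters(cloud)
  opt_plain <- options; opt_plain$use_shear <- FALSE
  opt_shear <- options; opt_shear$use_shear <- TRUE
  fit_plain <- fit_egg_both_ends(cloud, init, opt_plain)
  sel <- switch(shear,
                off = fit_plain,
                on = fit_egg_both_ends(cloud, init, opt_shear),
                auto = {
                  fit_sh <- fit_egg_both_ends(cloud, init, opt_shear)
                  if (!fit_plain$converged && !fit_sh$converged) fit_plain
                  else select_shear_model(fit_plain, fit_sh)
                })
  if (sel$converged) {
    sel$volume <- fit_volume(sel)
  }
  sel$init <- init
  sel
}

#' Volume and its standard deviation from a fit
#'
#' Applies the closed-form volume and first-order error propagation to a
#' converged fit's shape estimates and covariance.
#'
#' @param fit A converged `egg_fit`.
#' @return List with `V` and `sigma_V` (cubic meters).
#' @export
fit_volume <- function(fit) {
  if (!isTRUE(fit$converged)) stop("volume requires a converged fit")
  shape <- egg_shape(abs(fit$shape$a), abs(fit$shape$b))
  V <- egg_volume(shape)
  sigma_V <- if (!is.null(fit$cov)) {
    volume_sigma(shape, fit$cov["a", "a"], fit$cov["b", "b"],
                 fit$cov["a", "b"])
  } else {
    NA_real_
  }
  list(V = V, sigma_V = sigma_V)
}
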