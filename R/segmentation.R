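# Eggshell extraction from a raw range-camera frame (center window, Otsu
# intensity threshold, robust surface filter).

#' Segmentation configuration
#'
#' @param window_edge Edge length of the metric center window (m).
#' @param poly_order Order of the robust depth-surface polynomial (1 or 2).
#' @param reject_mult Residual rejection multiplier (times the robust scale
#'   1.4826 x MAD).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(window_edge = 0.30, poly_order = 2L, reject_mult = 20) {
  stopifnot(window_edge > 0, poly_order %in% c(1L, 2L), reject_mult > 0)
  structure(list(window_edge = window_edge, poly_order = as.integer(poly_order),
                 reject_mult = reject_mult), class = "seg_config")
}

#' Crop the metric center window
#'
#' Keeps the valid points whose lateral coordinates lie inside the
#' axis-aligned square of the given edge length, centered on the frame's
#' central ray (the sensor boresight, x = y = 0).  Bounds are half-open:
#' `[-edge/2, +edge/2)`.
#'
#' @param frame A `range_frame` or an [egg_cloud()].
#' @param edge Window edge length (m).
#' @return An [egg_cloud()] of the points inside the window.
#' @export
crop_center_window <- function(frame, edge = 0.30) {
  cloud <- if (inherits(frame, "range_frame")) frame_to_cloud(frame) else frame
  xyz <- cloud_xyz(cloud)
  if (nrow(xyz) == 0L) stop("empty frame")
  h <- edge / 2
  keep <- xyz[, 1] >= -h & xyz[, 1] < h & xyz[, 2] >= -h & xyz[, 2] < h
  if (!any(keep)) stop("no valid points inside the center window")
  out <- cloud_subset(cloud, keep)
  if (!is.null(attr(cloud, "label"))) {
    attr(out, "label") <- attr(cloud, "label")[keep]
  }
  out
}

#' Otsu intensity threshold
#'
#' Computes the threshold t maximizing the between-class variance of the
#' raw integer intensity histogram, with classes `{I <= t}` and `{I > t}`.
#' Ties are broken by the smallest t.  Working on the integer histogram
#' keeps the result bit-exact.
#'
#' @param intensities Non-negative integer intensity values.
#' @return The threshold (integer gray level).
#' @export
otsu_threshold <- function(intensities) {
  v <- as.integer(round(intensities))
  stopifnot(all(v >= 0))
  if (length(unique(v)) < 2L) stop("constant intensities: degenerate histogram")
  lev <- 0:max(v)
  h <- as.numeric(tabulate(v + 1L, nbins = length(lev)))
  n <- sum(h)
  w0 <- cumsum(h)                 # count in class {I <= t}
  m0 <- cumsum(h * lev)           # intensity sum in class {I <= t}
  mt <- m0[length(m0)]
  w1 <- n - w0
  # between-class variance w0*w1*(mu0 - mu1)^2 / n^2, up to the constant n^2
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, length(lev))
  bc[valid] <- (mt * w0[valid] - n * m0[valid])^2 / (w0[valid] * w1[valid])
  lev[which.max(bc)]
}

#' Split the egg from the stage by intensity
#'
#' Applies [otsu_threshold()] to the cloud's intensities and returns the
#' bright (above-threshold) class, assumed to be the eggshell against a
#' dark stage.
#'
#' @param cloud An [egg_cloud()] with intensities.
#' @return The bright-class [egg_cloud()]; the threshold used is attached
#'   as attribute `"threshold"`.
#' @export
split_egg_from_stage <- function(cloud) {
  if (is.null(cloud$intensity)) stop("cloud has no intensities")
  t <- otsu_threshold(cloud$intensity)
  keep <- cloud$intensity > t
  if (!any(keep)) stop("segmentation failure: bright class is empty")
  out <- cloud_subset(cloud, keep)
  if (!is.null(attr(cloud, "label"))) {
    attr(out, "label") <- attr(cloud, "label")[keep]
  }
  attr(out, "threshold") <- t
  out
}

# Bivariate polynomial design matrix in (x, y).
poly_design <- function(x, y, order) {
  if (order == 1L) cbind(1, x, y) else cbind(1, x, y, x^2, x * y, y^2)
}

#' Robust depth-surface outlier filter
#'
#' Fits a low-order polynomial depth surface `z = p(x, y)` by MM-type
#' robust regression (an S-estimator start followed by redescending
#' IRLS, [MASS::rlm()]), which resists both vertical outliers and
#' high-leverage points, then removes points whose
#' absolute residual exceeds `reject_mult` times the robust scale
#' (1.4826 x MAD of the residuals), and repeats on the survivors until the
#' inlier set stops changing (at most 10 rounds).
#'
#' @param cloud An [egg_cloud()] or n x 3 matrix.
#' @param config A [seg_config()].
#' @return The inlier [egg_cloud()]; removed indices are attached as
#'   attribute `"removed"`.
#' @export
robust_outlier_filter <- function(cloud, config = seg_config()) {
  xyz <- cloud_xyz(cloud)
  p <- if (config$poly_order == 1L) 3L else 6L
  if (nrow(xyz) < p) stop("too few points for the robust surface fit")
  keep <- rep(TRUE, nrow(xyz))
  for (round in 1:10) {
    X <- poly_design(xyz[keep, 1], xyz[keep, 2], config$poly_order)
    z <- xyz[keep, 3]
    beta <- robust_surface_coef(X, z)
    res_all <- xyz[, 3] - poly_design(xyz[, 1], xyz[, 2], config$poly_order) %*% beta
    s <- 1.4826 * stats::median(abs(res_all[keep] - stats::median(res_all[keep])))
    if (s <= 0) break
    new_keep <- abs(res_all) <= config$reject_mult * s
    if (sum(new_keep) < p) break
    if (identical(new_keep, keep)) { keep <- new_keep; break }
    keep <- new_keep
  }
  out <- cloud_subset(cloud, keep)
  if (!is.null(attr(cloud, "label"))) {
    attr(out, "label") <- attr(cloud, "label")[keep]
  }
  attr(out, "removed") <- which(!keep)
  out
}

# Leverage-robust polynomial surface coefficients: MM-estimation via
# MASS::rlm, falling back to ordinary least squares on degenerate input.
robust_surface_coef <- function(X, z) {
  beta <- tryCatch(
    suppressWarnings(stats::coef(MASS::rlm(X, z, method = "MM",
                                           maxit = 100))),
    error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) beta <- qr.coef(qr(X), z)
  beta
}

#' Extract the eggshell point cloud from a frame
#'
#' Full segmentation pipeline: metric center window, Otsu intensity split,
#' robust depth-surface outlier filter.
#'
#' @param frame A `range_frame` (or an [egg_cloud()] with intensities).
#' @param config A [seg_config()].
#' @return The eggshell [egg_cloud()].
#' @export
extract_egg <- function(frame, config = seg_config()) {
  cropped <- crop_center_window(frame, config$window_edge)
  bright <- split_egg_from_stage(cropped)
  robust_outlier_filter(bright, config)
}
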