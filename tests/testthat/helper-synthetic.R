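# Shared helpers: random regular shapes/poses and small fixtures built in
# code.  All randomness is seeded by the caller (withr::with_seed).

random_regular_shape <- function(a_range = c(0.03, 0.08)) {
  a <- stats::runif(1, a_range[1], a_range[2])
  egg_shape(a, stats::runif(1, 0.63, 0.77) * a)
}

random_scene <- function(seed, noise_sigma = 0, shear = shear_params(0, 0),
                         tilt_range = c(-20, 20), az_range = c(0, 180), ...) {
  withr::with_seed(seed, {
    scene_spec(shape = random_regular_shape(),
               tilt_deg = stats::runif(1, tilt_range[1], tilt_range[2]),
               azimuth_deg = stats::runif(1, az_range[1], az_range[2]),
               noise_sigma = noise_sigma, shear = shear, seed = seed + 1000L,
               ...)
  })
}

# finite-difference Jacobian of the packed-parameter residual vector
fd_jacobian_params <- function(points, theta, variant, h = 1e-7) {
  res_at <- function(th) {
    est <- eggfit:::params_unpack(th, variant)
    model_residual(points, est$shape, est$pose, variant, est$shear)
  }
  vapply(seq_along(theta), function(j) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (res_at(tp) - res_at(tm)) / (2 * h)
  }, numeric(nrow(eggfit:::cloud_xyz(points))))
}
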