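test_that("2D egg curve vanishes at its defining points", {
  sh <- egg_shape(0.05, 0.035)
  expect_equal(curve2d_residual(sh$a, 0, sh), 0)
  expect_equal(curve2d_residual(0, 0, sh), 0)
  # round-trip: the radius profile puts (t, r(t)) back on the curve
  t <- 0.025
  r <- sqrt(radius_profile(t, sh))
  expect_lt(abs(curve2d_residual(t, r, sh)), 1e-12)
})

test_that("radius profile matches its quadratic and a bisection oracle", {
  sh <- egg_shape(0.06, 0.042)
  expect_equal(radius_profile(0, sh), 0)
  expect_equal(radius_profile(sh$a, sh), 0)
  # b = 0 degenerates to the sphere of diameter a
  sph <- egg_shape(0.06, 0)
  expect_equal(radius_profile(0.03, sph), 0.03^2, tolerance = 1e-12)
  # independent bisection root search on the implicit curve in r^2
  t <- 0.03
  g <- function(u) (t^2 + u)^2 - sh$a * t^3 - (sh$a - sh$b) * t * u
  lo <- 0; hi <- sh$a^2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  expect_equal(radius_profile(t, sh), (lo + hi) / 2, tolerance = 1e-12)
  expect_error(radius_profile(sh$a * 1.5, sh), "must lie in")
})

test_that("closed-form volume equals the unsimplified expression and quadrature", {
  withr::with_seed(11, {
    for (i in 1:25) {
      sh <- egg_shape(runif(1, 0.02, 0.09), 0)
      sh$b <- runif(1, 0.05, 0.9) * sh$a
      a <- sh$a; b <- sh$b
      # raw closed form with the 1/b and 1/b^2 terms kept
      raw <- (pi / 2) * (a / (6 * b) * (a + b)^3 +
                           ((a - b)^5 - (a + b)^5) / (60 * b^2) -
                           a^3 / 6 - a^2 * b / 2)
      expect_equal(egg_volume(sh), raw, tolerance = 1e-12)
      quad <- pi * stats::integrate(function(t) radius_profile(t, sh), 0, a,
                                    rel.tol = 1e-12)$value
      expect_equal(egg_volume(sh), quad, tolerance = 1e-8)
    }
  })
})

test_that("b -> 0 volume limit is the sphere of diameter a", {
  a <- 0.057
  expect_equal(egg_volume(egg_shape(a, 1e-12 * a)), pi * a^3 / 6,
               tolerance = 1e-9)
  expect_equal(egg_volume(egg_shape(a, 0)), pi * a^3 / 6, tolerance = 1e-15)
})

test_that("volume gradient matches central differences; sigma_V behaves", {
  withr::with_seed(12, {
    for (i in 1:10) {
      sh <- random_regular_shape()
      g <- egg_volume_gradient(sh)
      h <- 1e-7
      fd_a <- (egg_volume(egg_shape(sh$a + h, sh$b)) -
                 egg_volume(egg_shape(sh$a - h, sh$b))) / (2 * h)
      fd_b <- (egg_volume(egg_shape(sh$a, sh$b + h)) -
                 egg_volume(egg_shape(sh$a, sh$b - h))) / (2 * h)
      expect_equal(g[["dV_da"]], fd_a, tolerance = 1e-6)
      expect_equal(g[["dV_db"]], fd_b, tolerance = 1e-6)
    }
  })
  sh <- egg_shape(0.06, 0.042)
  expect_equal(volume_sigma(sh, 0, 0, 0), 0)
  # monotone in var_a at zero covariance
  s1 <- volume_sigma(sh, 1e-8, 2e-8, 0)
  s2 <- volume_sigma(sh, 2e-8, 2e-8, 0)
  expect_gte(s2, s1)
  expect_error(volume_sigma(sh, 1e-8, 1e-8, 1e-6), "covariance")
})

test_that("regular-shape gate is the 10% band around b/a = 0.7", {
  expect_true(is_regular_shape(egg_shape(1, 0.7)))
  expect_true(is_regular_shape(egg_shape(1, 0.63)))
  expect_true(is_regular_shape(egg_shape(1, 0.77)))
  expect_false(is_regular_shape(egg_shape(1, 0.62)))
  expect_false(is_regular_shape(egg_shape(1, 0.78)))
})

test_that("sensor-to-object transform: identity, tip, and exact inverse", {
  withr::with_seed(13, {
    P <- matrix(rnorm(30, sd = 0.1), ncol = 3)
    id <- egg_pose()
    for (ax in c("I", "II", "III")) {
      va <- model_variant(ax)
      expect_equal(sensor_to_object(P, id, va), P,
                   ignore_attr = TRUE, tolerance = 1e-15)
      pose <- egg_pose(0.02, -0.01, 0.7, omega = 0.4, psi = -0.3, phi = 0.25)
      tip <- matrix(c(pose$xc, pose$yc, pose$zc), 1)
      expect_equal(as.numeric(sensor_to_object(tip, pose, va)), c(0, 0, 0),
                   tolerance = 1e-15)
      U <- sensor_to_object(P, pose, va)
      expect_equal(object_to_sensor(U, pose, va), P,
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
  })
})

test_that("back-shear is the exact affine inverse of the forward shear", {
  sh <- shear_params(0.1, -0.05)
  out <- back_shear(1, 2, 10, sh)
  expect_equal(out$x, 0)
  expect_equal(out$y, 2.5)
  none <- back_shear(1, 2, 10, shear_params(0, 0))
  expect_equal(c(none$x, none$y), c(1, 2))
  # forward then back is the identity
  withr::with_seed(14, {
    x <- rnorm(5); y <- rnorm(5); z <- rnorm(5)
    fx <- x + sh$sh_x * z; fy <- y + sh$sh_y * z
    bs <- back_shear(fx, fy, z, sh)
    expect_equal(bs$x, x, tolerance = 1e-15)
    expect_equal(bs$y, y, tolerance = 1e-15)
  })
})

test_that("model residual vanishes on generator output, including shear", {
  shp <- egg_preset("chicken")
  pose <- egg_pose(0.01, -0.02, 0.74, psi = 0.2, phi = -0.15)
  va <- model_variant("II")
  cl <- sample_surface(shp, pose, va, 300, seed = 21)
  expect_lt(max(abs(model_residual(cl, shp, pose, va))), 1e-10)
  shr <- shear_params(0.03, -0.02)
  cl2 <- sample_surface(shp, pose, va, 300, seed = 21, shear = shr)
  expect_lt(max(abs(model_residual(cl2, shp, pose, va, shr))), 1e-10)
  # the egg tip (object-space origin) satisfies every variant
  for (ax in c("I", "II", "III")) {
    tip <- matrix(c(pose$xc, pose$yc, pose$zc), 1)
    expect_equal(model_residual(tip, shp, pose, model_variant(ax)), 0,
                 tolerance = 1e-18)
  }
})

test_that("Model I and II are the same formula under axis relabelling", {
  withr::with_seed(15, {
    shp <- random_regular_shape()
    P <- matrix(rnorm(60, sd = 0.03), ncol = 3)
    phi <- 0.3; psi <- -0.2; tip <- c(0.01, 0.02, -0.01)
    pose2 <- egg_pose(tip[1], tip[2], tip[3], phi = phi, psi = psi)
    r2 <- model_residual(P, shp, pose2, model_variant("II"))
    # swap X and Y of points and tip; remap (phi, psi) -> (omega, psi)
    S <- P[, c(2, 1, 3)]
    pose1 <- egg_pose(tip[2], tip[1], tip[3], omega = -phi, psi = -psi)
    r1 <- model_residual(S, shp, pose1, model_variant("I"))
    expect_equal(r1, r2, tolerance = 1e-14)
  })
})

test_that("volume depends on shape only: pose and shear leave V unchanged", {
  spec <- scene_spec(seed = 31, noise_sigma = 0, tilt_deg = 12,
                     azimuth_deg = 25)
  hs <- render_half_shell(spec)
  f1 <- estimate_egg_volume(hs$cloud, shear = "off")
  # rigidly transformed copy of the same cloud
  Rr <- eggfit:::rot_z(0.4) %*% eggfit:::rot_x(0.2)
  P2 <- sweep(hs$cloud$xyz %*% t(Rr), 2, c(0.04, -0.02, 0.03), `+`)
  f2 <- estimate_egg_volume(P2, shear = "off")
  # shear-distorted copy, fitted with shear compensation
  spec_sh <- scene_spec(shape = spec$shape, pose = spec$pose,
                        variant = spec$variant, noise_sigma = 0,
                        shear = shear_params(0.03, -0.02), seed = 31)
  f3 <- estimate_egg_volume(render_half_shell(spec_sh)$cloud, shear = "on")
  V <- egg_volume(spec$shape)
  expect_equal(fit_volume(f1)$V, V, tolerance = 3e-3)
  expect_equal(fit_volume(f2)$V, V, tolerance = 3e-3)
  expect_equal(fit_volume(f3)$V, V, tolerance = 3e-3)
})

test_that("volume is more sensitive to a than to b for larger regular eggs", {
  for (a in seq(0.031, 0.09, length.out = 25)) {
    g <- egg_volume_gradient(egg_shape(a, 0.7 * a))
    expect_gt(abs(g[["dV_da"]]), abs(g[["dV_db"]]))
  }
})
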