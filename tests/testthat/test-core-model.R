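test_that("terminal velocity follows Stokes balance, signed by density mismatch", {
  # frozen from direct evaluation of 2 g r^2 (rho_B - rho_P) / (9 eta)
  expect_equal(terminal_velocity(ps5(), buffer_spec(997, 1e-3)),
               -3.9785e-06, tolerance = 1e-6)
  expect_equal(terminal_velocity(hbmsc(), buffer_spec(1000, 1e-3)),
               -1.433912e-05, tolerance = 1e-6)
  # neutral buoyancy
  expect_identical(terminal_velocity(particle_spec(5e-6, 1000),
                                     buffer_spec(1000, 1e-3)), 0)
  # lighter-than-buffer particles float
  expect_gt(terminal_velocity(particle_spec(5e-6, 950),
                              buffer_spec(1000, 1e-3)), 0)
  expect_error(particle_spec(-1e-6, 1000), "positive")
  expect_error(buffer_spec(1000, 0), "positive")
})

test_that("Stokes relaxation time is microseconds for micron-scale particles", {
  # frozen from m / (6 pi eta r) with m = (4/3) pi r^3 rho
  expect_equal(stokes_relaxation_time(ps5(), buffer_spec(997, 1e-3)),
               5.944e-6, tolerance = 1e-3)
  expect_equal(stokes_relaxation_time(hbmsc(), buffer_spec(1000, 1e-3)),
               2.504e-5, tolerance = 1e-3)
  # massless limit
  expect_equal(stokes_relaxation_time(particle_spec(1e-12, 1070),
                                      buffer_spec(997, 1e-3)), 0,
               tolerance = 1e-15)
})

test_that("effective areas match geometry limits and a Monte-Carlo oracle", {
  R <- 1
  expect_equal(effective_area_lens(R, 0), pi * R^2)
  expect_equal(effective_area_lens(R, 2 * R), 0)
  expect_equal(effective_area_lens(R, 5 * R), 0)  # clamped past depletion
  expect_equal(effective_area_segment(R, 0), pi * R^2 / 2)
  expect_equal(effective_area_segment(R, R), 0)

  # lens: intersection of unit disks centred (0,0) and (0,1)
  lens <- mc_area(1e6, c(-1, 1), c(-1, 2), function(x, y)
    x^2 + y^2 < 1 & x^2 + (y - 1)^2 < 1)
  expect_lt(abs(effective_area_lens(1, 1) - lens$area), 3 * lens$se)
  expect_equal(effective_area_lens(1, 1), 1.2284, tolerance = 1e-4)

  # segment of the unit disk above y = 0.5
  seg <- mc_area(1e6, c(-1, 1), c(-1, 1), function(x, y)
    x^2 + y^2 < 1 & y > 0.5)
  expect_lt(abs(effective_area_segment(1, 0.5) - seg$area), 3 * seg$se)
  expect_equal(effective_area_segment(1, 0.5), 0.6142, tolerance = 1e-4)

  expect_error(effective_area_lens(1, -0.1), ">= 0")
})

test_that("boundary concentration curves equal their area ratios and are monotone", {
  v <- 4e-6; R <- 2.3e-3
  t <- seq(0, 2 * R / v, length.out = 101)
  up <- concentration_ratio_upper(v, R, t)
  expect_equal(up, effective_area_lens(R, v * t) / (pi * R^2),
               tolerance = 1e-12)
  t2 <- seq(0, R / v, length.out = 101)
  lo <- concentration_ratio_lower(v, R, t2)
  expect_equal(lo, effective_area_segment(R, v * t2) / (pi * R^2 / 2),
               tolerance = 1e-12)

  # monotone non-increasing, in [0, 1], upper >= lower on a common grid
  tt <- seq(0, 3 * R / v, length.out = 200)
  u <- concentration_ratio_upper(v, R, tt)
  l <- concentration_ratio_lower(v, R, tt)
  expect_true(all(diff(u) <= 1e-12))
  expect_true(all(diff(l) <= 1e-12))
  expect_true(all(u >= 0 & u <= 1 & l >= 0 & l <= 1))
  expect_true(all(u >= l - 1e-12))

  # frozen spot value at half the depletion argument
  expect_equal(concentration_ratio_upper(v, R, R / v), 0.3910,
               tolerance = 1e-4)
  expect_equal(concentration_ratio_lower(v, R, 0.5 * R / v), 0.3910,
               tolerance = 1e-4)

  # no sedimentation sentinel
  expect_equal(concentration_ratio_upper(0, R, tt), rep(1, length(tt)))
})

test_that("half-life boundary coefficients solve C/C0 = 1/2 with a 2x ratio", {
  k <- half_life_boundary_coefficients()
  expect_equal(unname(k["upper"] / k["lower"]), 2)  # exact by construction
  expect_equal(unname(round(k["lower"], 1)), 0.4)
  expect_equal(unname(round(k["upper"], 1)), 0.8)
  expect_equal(unname(k["lower"]), 0.40397, tolerance = 1e-4)
  # each solves its boundary equation
  expect_lt(abs(concentration_ratio_lower(1, 1, k[["lower"]]) - 0.5), 1e-10)
  expect_lt(abs(concentration_ratio_upper(1, 1, k[["upper"]]) - 0.5), 1e-10)
})

test_that("half-life bounds scale with R_S and density mismatch", {
  b <- buffer_spec(997, 1e-3)
  hb <- half_life_bounds(ps5(), b, syr_1ml())
  expect_equal(hb$lower_bound, 233.5, tolerance = 1e-3)
  expect_equal(hb$upper_bound, 467.1, tolerance = 1e-3)

  # doubling R_S doubles both bounds
  s2 <- syringe_spec(4.6e-3, 40e-3, 0.5e-3, 5e-3)
  hb2 <- half_life_bounds(ps5(), b, s2)
  expect_equal(hb2$lower_bound / hb$lower_bound, 2, tolerance = 1e-10)

  # halving the density mismatch doubles both bounds
  p_half <- particle_spec(5e-6, 997 + (1070 - 997) / 2)
  hb3 <- half_life_bounds(p_half, b, syr_1ml())
  expect_equal(hb3$upper_bound / hb$upper_bound, 2, tolerance = 1e-10)

  # neutral buoyancy: infinite half-life sentinel
  hb4 <- half_life_bounds(particle_spec(5e-6, 997), b, syr_1ml())
  expect_identical(hb4$lower_bound, Inf)
})

test_that("half-life estimate and sedimentation constant are inverses", {
  b <- buffer_spec(1000, 1e-3)
  t4 <- half_life_estimate(ps5(), b, syr_1ml(), K_S = 0.4)
  t8 <- half_life_estimate(ps5(), b, syr_1ml(), K_S = 0.8)
  expect_equal(t8 / t4, 2)
  v <- abs(terminal_velocity(ps5(), b))
  expect_equal(sedimentation_constant(t4, v, 2.3e-3), 0.4, tolerance = 1e-12)
  expect_equal(sedimentation_constant(100, 1e-5, 2e-3), 0.5)
  expect_equal(sedimentation_constant(0, 1e-5, 2e-3), 0)
  expect_warning(half_life_estimate(ps5(), b, syr_1ml(), K_S = 1.2),
                 "outside the model range")
  expect_error(sedimentation_constant(10, 0, 2e-3), "positive")
})

test_that("K_S fitting recovers exact and noisy through-origin slopes", {
  pred <- data.frame(R_S = c(1e-3, 2e-3, 3e-3, 2.3e-3),
                     v_T_mag = c(4e-6, 3e-6, 5e-6, 1e-5))
  pts <- transform(pred, t_half = 0.5 * R_S / v_T_mag)
  fit <- fit_sedimentation_constant(pts)
  expect_equal(fit$K_S, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # symmetric noise around a single predictor value: closed-form slope
  eps <- 3
  pts2 <- data.frame(R_S = 2e-3, v_T_mag = 1e-5,
                     t_half = c(100 - eps, 100 + eps))
  fit2 <- fit_sedimentation_constant(pts2)
  expect_equal(fit2$K_S, 100 / 200, tolerance = 1e-12)

  expect_error(fit_sedimentation_constant(pts2[1, ]), "at least 2")
})

test_that("Einstein viscosity increment is linear and negligible at bench loads", {
  b <- buffer_spec(1000, 1e-3)
  p3 <- particle_spec(3e-6, 1070)
  inc <- einstein_viscosity_increment(p3, 1e12, b)  # 1e6 particles/ml
  expect_equal(inc, 2.827e-7, tolerance = 1e-3)
  expect_lt(inc, 1e-6)  # < 1e-3 mPa s
  expect_equal(einstein_viscosity_increment(p3, 0, b), 0)
  expect_equal(einstein_viscosity_increment(p3, 2e12, b), 2 * inc)
})

test_that("boundary_curve wraps the analytic models with provenance", {
  b <- buffer_spec(997, 1e-3)
  tt <- seq(0, 1000, by = 10)
  cu <- boundary_curve(ps5(), b, syr_1ml(), tt, "upper")
  cl <- boundary_curve(ps5(), b, syr_1ml(), tt, "lower")
  expect_s3_class(cu, "concentration_curve")
  expect_identical(cu$source, "analytic_upper")
  expect_equal(cu$ratio[1], 1)
  v <- abs(terminal_velocity(ps5(), b))
  expect_equal(cu$ratio, concentration_ratio_upper(v, 2.3e-3, tt))
  expect_equal(cl$effective_area[1], pi * 2.3e-3^2 / 2)
})
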