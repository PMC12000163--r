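test_that("Poiseuille profile has the frozen axis value, no-slip and flux Q", {
  s <- syr_1ml()
  Q <- ul_min(10)
  # frozen from 2 Q / (pi R_S^2)
  v_axis <- poiseuille_velocity(s, Q, c(0, 0, 0.01))
  expect_equal(v_axis[3], 2.0057e-5, tolerance = 1e-4)
  expect_equal(v_axis[1:2], c(0, 0))
  # no-slip at the wall
  v_wall <- poiseuille_velocity(s, Q, c(s$barrel_radius, 0, 0.01))
  expect_equal(v_wall[3], 0, tolerance = 1e-12)
  expect_error(poiseuille_velocity(s, Q, c(3e-3, 0, 0.01)), "outside")
})

test_that("point sink has the frozen magnitude, inverse-square decay, radial direction", {
  Q <- ul_min(10)
  ctr <- c(0, 0, 0.04)
  # frozen from Q / (2 pi r^2)
  v1 <- sink_velocity(ctr, Q, c(0, 1e-3, 0.04))
  expect_equal(sqrt(sum(v1^2)), 2.6526e-5, tolerance = 1e-4)
  v2 <- sink_velocity(ctr, Q, c(0, 2e-3, 0.04))
  expect_equal(sqrt(sum(v1^2)) / sqrt(sum(v2^2)), 4, tolerance = 1e-10)
  # directly above the outlet, the pull is straight down
  expect_equal(v1[c(1, 3)], c(0, 0))
  expect_lt(v1[2], 0)
  # cap limits the magnitude inside one outlet radius
  v_in <- sink_velocity(ctr, Q, c(0, 1e-4, 0.04), cap_radius = 5e-4)
  v_cap <- sink_velocity(ctr, Q, c(0, 5e-4, 0.04), cap_radius = 5e-4)
  expect_equal(sqrt(sum(v_in^2)), sqrt(sum(v_cap^2)), tolerance = 1e-10)
})

test_that("superposition field conserves flux, matches Poiseuille upstream, zero at Q=0", {
  s <- syr_flow()
  Q <- ul_min(10)
  f <- build_flow_field(s, Q)
  # mass conservation within 2% at stations spanning the barrel
  for (z in c(0.005, 0.02, 0.035, 0.0395))
    expect_equal(cross_section_flux(f, z) / Q, 1, tolerance = 0.02)
  # far upstream (> 5 R_S from the outlet): pure Poiseuille, no vertical flow
  pts <- cbind(c(0, 1e-3, -0.8e-3), c(0, 0.5e-3, 1.2e-3), 0.01)
  v <- f$evaluate(pts)
  expect_equal(v, poiseuille_velocity(s, Q, pts), tolerance = 0.01)
  vbar <- Q / (pi * s$barrel_radius^2)
  expect_true(all(abs(v[, 2]) < 0.01 * vbar))
  # Q = 0 gives the zero field
  f0 <- build_flow_field(s, 0)
  expect_equal(f0$evaluate(pts), matrix(0, 3, 3))
  expect_equal(cross_section_flux(f0, 0.02), 0)
})

test_that("axisymmetric Stokes solve: flux, no-slip, Poiseuille far field", {
  s <- syr_flow()
  Q <- ul_min(10)
  f <- build_flow_field(s, Q, "stokes_axisym")
  # mass conservation within 0.5% away from the immediate outlet vicinity
  for (z in c(0.005, 0.02, 0.035))
    expect_equal(cross_section_flux(f, z) / Q, 1, tolerance = 0.005)
  vbar <- Q / (pi * s$barrel_radius^2)
  # no-slip: wall speed below 1% of the mean axial velocity
  v_wall <- f$evaluate(matrix(c(s$barrel_radius * 0.999, 0, 0.02), 1, 3))
  expect_lt(sqrt(sum(v_wall^2)), 0.01 * vbar)
  # axis velocity matches the Poiseuille maximum upstream
  v_axis <- f$evaluate(matrix(c(0, 0, 0.015), 1, 3))
  expect_equal(v_axis[3], 2 * vbar, tolerance = 0.01)
  # vertical component negligible far upstream of the outlet
  v_up <- f$evaluate(matrix(c(1e-3, 0.5e-3, 0.01), 1, 3))
  expect_lt(abs(v_up[2]), 0.01 * vbar)
  # eccentric outlets are not supported by this backend
  expect_error(build_flow_field(syr_flow(offset = -1.7e-3), Q,
                                "stokes_axisym"), "concentric")
})

test_that("flow field exports as tabular text with provenance", {
  f <- build_flow_field(syr_flow(), ul_min(10))
  path <- tempfile(fileext = ".tsv")
  out <- export_flow_field(f, path, nx = 5, ny = 5, nz = 5)
  expect_true(file.exists(path))
  lines <- readLines(path)
  expect_true(any(grepl("^# backend: superposition", lines)))
  dat <- utils::read.table(path, header = FALSE, skip = 4)
  expect_equal(nrow(dat), nrow(out))
  expect_equal(ncol(dat), 6)
})
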