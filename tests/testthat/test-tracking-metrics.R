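test_that("particle advection: exact transport in simple fields", {
  # uniform steady velocity: z(t) = z0 + v0 (t - t0) to integrator tolerance
  v0 <- 20e-6
  traj <- advect_particle(function(x, z, t) list(ur = 0, uz = v0),
                          x0 = c(0, 1e-3), t0 = 0.5, duration = 2,
                          dt = 2 / 500)
  expect_equal(tail(traj$z, 1), 1e-3 + v0 * 2, tolerance = 1e-12)
  expect_equal(tail(traj$t, 1), 2.5)
  # spatially uniform sinusoid: closed orbit, net drift < 1e-6 of amplitude
  f <- 8.67; A <- 1e-3
  traj2 <- advect_particle(
    function(x, z, t) list(ur = 0, uz = A * sin(2 * pi * f * t)),
    x0 = c(0, 0), t0 = 0, duration = 1 / f, dt = 1 / (1000 * f))
  orbit_amp <- diff(range(traj2$z))
  expect_lt(abs(tail(traj2$z, 1) - traj2$z[1]), 1e-6 * orbit_amp)
  # exit flag for a particle leaving the domain
  traj3 <- advect_particle(function(x, z, t) list(ur = 0, uz = 1),
                           x0 = c(0, 0), t0 = 0, duration = 10, dt = 0.01,
                           inside = function(x, z, t) z < 1)
  expect_true(attr(traj3, "exited"))
  expect_lt(tail(traj3$z, 1), 1.02)
})

test_that("flow decomposition separates mean and oscillatory components", {
  f <- 8.67
  t <- seq(0, 2 / f, length.out = 1601L)
  # constant velocity: mean 20, oscillatory 0, ratio Inf
  d <- decompose_flow(rep(20e-6, length(t)), f, t = t)
  expect_equal(d$mean_flow_speed, 20e-6)
  expect_equal(d$oscillatory_velocity, 0)
  expect_identical(d$ratio, Inf)
  # pure sinusoid amplitude 5: mean ~ 0, peak-to-peak 10
  v <- 5e-6 * sin(2 * pi * f * t)
  d2 <- decompose_flow(v, f, t = t)
  expect_lt(abs(d2$mean_flow_speed), 1e-9)
  expect_equal(d2$oscillatory_velocity, 10e-6, tolerance = 1e-5)
  # the in-vivo-like regime: mean ~ 20 um/s with ~10 um/s oscillation
  d3 <- decompose_flow(20e-6 + 5e-6 * sin(2 * pi * f * t), f, t = t)
  expect_equal(d3$mean_flow_speed, 20e-6, tolerance = 1e-6)
  expect_equal(d3$oscillatory_velocity, 10e-6, tolerance = 1e-5)
  expect_equal(d3$ratio, 2, tolerance = 1e-4)
  # sub-cycle series rejected
  expect_error(decompose_flow(v[t < 0.5 / f], f, t = t[t < 0.5 / f]),
               "full cycle")
  # trajectory-based decomposition: drift + orbit
  traj <- advect_particle(
    function(x, z, t) list(ur = 0, uz = 20e-6 + 5e-6 * sin(2 * pi * f * t)),
    x0 = c(0, 0), t0 = 0, duration = 2 / f, dt = 1 / (1000 * f))
  dt_ <- decompose_flow(traj, f)
  expect_equal(dt_$mean_flow_speed, 20e-6, tolerance = 1e-6)
  expect_equal(dt_$oscillatory_velocity, 10e-6, tolerance = 1e-3)
})

test_that("phase difference: lag convention, wrap-around and shift invariance", {
  f <- 8.67; om <- 2 * pi * f
  # uniform sampling over whole cycles without a duplicated endpoint keeps
  # the Fourier projection leakage-free
  t <- (0:1999) / 2000 * 3 / f
  wall <- sin(om * t)
  # identical series: 0 degrees
  expect_equal(phase_difference(wall, wall, f, t), 0, tolerance = 1e-8)
  # fluid delayed by a quarter period lags by 90 degrees
  expect_equal(phase_difference(wall, sin(om * (t - 0.25 / f)), f, t), 90,
               tolerance = 1e-6)
  # fluid advanced by a quarter period: lag wraps to 270 degrees
  expect_equal(phase_difference(wall, sin(om * (t + 0.25 / f)), f, t), 270,
               tolerance = 1e-6)
  # the peristaltic pattern: wall ~ -cos, fluid ~ +sin gives 270
  expect_equal(phase_difference(-cos(om * t), sin(om * t), f, t), 270,
               tolerance = 1e-6)
  # invariant under a uniform time shift of both series
  ts <- t + 0.1234
  expect_equal(phase_difference(sin(om * ts), sin(om * (ts - 0.25 / f)), f, ts),
               90, tolerance = 1e-6)
  # flat series: phase undefined
  expect_error(phase_difference(rep(0, 100), rep(0, 100), f, t[1:100]),
               "noise floor")
})

test_that("pathline displacement equals v dt for steady fields (streakline equivalence)", {
  sol <- cached_wave_solution(0.004, m = 1L)
  # freeze the field at t = 0: steady-field pathline over a short dt
  fld <- wave_frame_field(sol)
  frozen <- function(x, z, t) fld(x, z, 0)
  v <- fld(50e-6, sol$spec$lambda / 4, 0)
  traj <- advect_particle(frozen, x0 = c(50e-6, sol$spec$lambda / 4),
                          duration = 1e-4, dt = 1e-5)
  expect_equal(tail(traj$z, 1) - traj$z[1], v$uz * 1e-4, tolerance = 1e-3)
})

test_that("L2 error norms: zero for identical solutions, decreasing under refinement", {
  s1 <- cached_wave_solution(0.004, m = 1L)
  s2 <- cached_wave_solution(0.004, m = 2L)
  self <- l2_error_norms(s2, s2)
  expect_equal(self$L2Err_v, 0, tolerance = 1e-12)
  expect_equal(self$L2Err_p, 0, tolerance = 1e-12)
  e12 <- l2_error_norms(s1, s2)
  expect_gt(e12$L2Err_v, 0)
  expect_gt(e12$L2Err_p, 0)
  # mismatched configurations rejected
  s1r <- cached_wave_solution(0.002, m = 1L)
  expect_error(l2_error_norms(s1r, s2), "different physical configurations")
})
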