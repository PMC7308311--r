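test_that("traveling sinusoid: amplitude, phase and exact wavelength bookkeeping", {
  spec <- wave_spec(0.004, c = 1, f = 8.67)
  expect_identical(spec$lambda * spec$f, spec$c)       # lambda f = c exactly
  expect_error(wave_spec(-0.1), "phi0")
  expect_error(wave_spec(1.2), "phi0")

  R1 <- 30e-6
  # zero at the wave front z = c t
  expect_equal(sinusoidal_displacement(spec, R1, z = 0.25, t = 0.25)$ur, 0)
  # peak phi0*R1 a quarter wavelength ahead
  d <- sinusoidal_displacement(spec, R1, z = spec$lambda / 4, t = 0)
  expect_equal(d$ur, 0.004 * R1, tolerance = 1e-12)
  expect_equal(d$ur, 0.12e-6, tolerance = 1e-12)
  # axial component identically zero
  zs <- seq(0, spec$lambda, length.out = 23L)
  expect_true(all(sinusoidal_displacement(spec, R1, zs, 0.01)$uz == 0))
  # zero amplitude -> zero displacement and velocity everywhere
  z0 <- wave_spec(0)
  expect_true(all(sinusoidal_displacement(z0, R1, zs, 0.3)$ur == 0))
  expect_true(all(sinusoidal_wall_velocity(z0, R1, zs, 0.3)$vr == 0))
  # analytic velocity matches centered differences to O(dt^2)
  dt <- 1e-6
  vfd <- (sinusoidal_displacement(spec, R1, zs, 0.1 + dt)$ur -
          sinusoidal_displacement(spec, R1, zs, 0.1 - dt)$ur) / (2 * dt)
  va <- sinusoidal_wall_velocity(spec, R1, zs, 0.1)$vr
  expect_equal(vfd, va, tolerance = 1e-6)
})

test_that("amplitude conventions convert consistently", {
  # 1-4% peak-to-peak of radius <-> half-wave fraction 0.005-0.02
  expect_equal(amp_from_pp_radius_pct(c(1, 4)), c(0.005, 0.02))
  expect_equal(pp_radius_pct_from_amp(amp_from_pp_radius_pct(2.7)), 2.7)
  expect_equal(amp_from_halfwave_pct(0.8), 0.008)
  # displacement amplitude for 1-4% pp of diameter: a in [0.3, 1.2] um
  a <- amp_from_pp_radius_pct(c(1, 4)) * 2 * 30e-6
  expect_equal(a, c(0.3e-6, 1.2e-6))
})

test_that("synthetic cardiac waveform is periodic, normalised, single-peaked", {
  f <- 8.67
  wf <- synth_pulse_waveform(f)
  expect_equal(wf$period, 1 / f)
  expect_equal(wf$period, 0.11534, tolerance = 1e-4)
  tt <- seq(0, wf$period, length.out = 2048L)
  # periodicity to 1e-12
  expect_lt(max(abs(wf$an(tt) - wf$an(tt + 1 / f))), 1e-12)
  # normalisation and bounded time average
  expect_equal(max(abs(wf$an(tt))), 1, tolerance = 1e-3)
  expect_lt(abs(mean(wf$an(tt[-length(tt)]))), 0.2)
  # single systolic peak per cycle: one sign change pair in the derivative
  dv <- wf$dan(tt[-length(tt)])
  expect_equal(sum(diff(sign(dv)) != 0), 2)
  # fast upstroke: rise time < decay time
  ipk <- which.max(wf$an(tt)); itr <- which.min(wf$an(tt))
  rise <- (tt[ipk] - tt[itr]) %% wf$period
  expect_lt(rise, wf$period / 2)
  # analytic derivative vs finite differences
  dt <- 1e-7
  expect_equal(wf$dan(tt), (wf$an(tt + dt) - wf$an(tt - dt)) / (2 * dt),
               tolerance = 1e-5)
  # pure cosine shape is admissible
  wc <- synth_pulse_waveform(f, shape = "cosine")
  expect_equal(wc$an(tt), cos(2 * pi * f * tt), tolerance = 1e-12)
  expect_error(synth_pulse_waveform(f, upstroke_frac = 1.5), "upstroke_frac")
  expect_error(synth_pulse_waveform(-1), "f must be positive")
})

test_that("waveform CSV round-trip preserves the shape", {
  wf <- synth_pulse_waveform(8.67)
  path <- tempfile(fileext = ".csv")
  write_waveform_csv(wf, path, n = 400L)
  wf2 <- read_waveform_csv(path, f = 8.67, n_harmonics = 3L)
  tt <- seq(0, wf$period, length.out = 333L)
  expect_equal(wf2$an(tt), wf$an(tt), tolerance = 1e-4)
  unlink(path)
})

test_that("region-resolved wall displacement: signs, scales and smooth blend", {
  built <- build_lobed_section(30e-6, target_edge_length = 2e-6)
  bp <- lobed_boundary_points(built)
  expect_setequal(unique(bp$region),
                  c("inner_wall", "outer_wall", "transition"))
  # normals are unit
  expect_equal(bp$nx^2 + bp$ny^2, rep(1, nrow(bp)), tolerance = 1e-12)
  wf <- synth_pulse_waveform(8.67)
  # pick a time/place where an = max = 1
  tt <- seq(0, wf$period, length.out = 4096L)
  tpk <- tt[which.max(wf$an(tt))]
  a <- 0.3e-6
  d <- wall_displacement_3d(wf, bp, z = 0, t = tpk, a = a, phi_sas = 0.368)
  mag <- sqrt(d$ux^2 + d$uy^2)
  anpk <- wf$an(tpk)
  inner <- bp$region == "inner_wall"; outer <- bp$region == "outer_wall"
  trans <- bp$region == "transition"
  # inner wall: |u| = a*an, directed against the outward normal
  expect_equal(mag[inner], rep(a * anpk, sum(inner)), tolerance = 1e-6)
  expect_lt(max(d$ux[inner] * bp$nx[inner] + d$uy[inner] * bp$ny[inner]), 0)
  # inner wall displacement points radially outward (dilation narrows PVS)
  expect_gt(min(d$ux[inner] * bp$x[inner] + d$uy[inner] * bp$y[inner]), 0)
  # outer wall: |u| = phi * a * an along +n
  expect_equal(mag[outer], rep(0.368 * a * anpk, sum(outer)),
               tolerance = 1e-6)
  # transition: magnitudes between the wall values
  expect_true(all(mag[trans] <= a * anpk * (1 + 1e-9)))
  # rigid outer wall: zero displacement at all times
  d0 <- wall_displacement_3d(wf, bp[outer, ], z = 0, t = 0.04, a = a,
                             phi_sas = 0)
  expect_true(all(abs(d0$ux) < 1e-20 & abs(d0$uy) < 1e-20))
  # unlabeled point rejected
  bad <- bp[1, ]; bad$region <- "elsewhere"
  expect_error(wall_displacement_3d(wf, bad, 0, 0, a), "region")
})

test_that("quintic smooth step is a C2 step", {
  expect_equal(smoothstep_quintic(c(0, 0.5, 1)), c(0, 0.5, 1))
  expect_equal(smoothstep_quintic(c(-3, 4)), c(0, 1))
  h <- 1e-4
  # zero first derivative at both ends
  expect_lt(abs(smoothstep_quintic(h) - smoothstep_quintic(0)) / h, 1e-6)
  expect_lt(abs(smoothstep_quintic(1) - smoothstep_quintic(1 - h)) / h, 1e-6)
})
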