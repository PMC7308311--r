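test_that("short-domain model constants are geometry-consistent", {
  mdl <- short_domain_model("annulus", phi_sas = 0.368)
  expect_equal(mdl$R_flow, annular_resistance(30e-6, 70e-6, 1e-3))
  expect_equal(mdl$A0, pi * (70e-6^2 - 30e-6^2))
  expect_equal(mdl$S, 2 * pi * (0.368 * 70e-6 - 30e-6))
  mdL <- short_domain_model("lobed", phi_sas = 0.368)
  # lobed resistance exceeds the annular one (side walls), area is smaller
  expect_gt(mdL$R_flow, mdl$R_flow)
  expect_lt(mdL$A0, mdl$A0)
  # rigid outer wall: area shrinks on dilation through the inner wall only
  mdR <- short_domain_model("annulus", phi_sas = 0)
  expect_equal(mdR$S, -2 * pi * 30e-6)
})

test_that("wall motion alone pumps negligibly; oscillation tunes to the in-vivo range", {
  wf <- synth_pulse_waveform(8.67)
  mdl <- short_domain_model("lobed")
  a <- tune_short_domain_amplitude(mdl, wf, target_osc = 15e-6)
  r0 <- run_short_domain(mdl, wf, a, p1 = 0)
  osc <- r0$decomposition$oscillatory_velocity
  expect_gt(osc, 10e-6); expect_lt(osc, 20e-6)
  # the "0.007 um/s" regime: mean far below 0.1 um/s by either estimate
  expect_lt(abs(r0$decomposition$mean_flow_speed), 0.1e-6)
  expect_lt(abs(r0$decomposition_particle$mean_flow_speed), 0.1e-6)
  # fluid in phase with the wall velocity (within +-30 deg of 0)
  ph <- r0$phase_deg
  expect_lt(min(ph, 360 - ph), 30)
})

test_that("mean flow is linear in the applied pressure through the origin", {
  wf <- synth_pulse_waveform(8.67)
  mdl <- short_domain_model("lobed")
  a <- tune_short_domain_amplitude(mdl, wf)
  p1s <- c(0, 0.005, 0.01, 0.02) * 133.322
  means <- vapply(p1s, function(p)
    run_short_domain(mdl, wf, a, p1 = p)$decomposition$mean_flow_speed, 0)
  # slope from the largest pressure; all points collinear through ~0
  slope <- means[4] / p1s[4]
  expect_equal(means[2], slope * p1s[2], tolerance = 1e-3)
  expect_equal(means[3], slope * p1s[3], tolerance = 1e-3)
  expect_lt(abs(means[1]), 1e-3 * means[4])
  # 0.01 mmHg drives the steady lobed-section mid-gap speed
  built <- build_lobed_section(30e-6, target_edge_length = 2e-6)
  lp <- lobed_poiseuille(built, 1e-3, dp = 0.01 * 133.322, L = 5e-3)
  expect_equal(means[3], lp$v_mid, tolerance = 1e-3)
  # particle-derived and probe-derived means agree for pressure-driven flow
  r <- run_short_domain(mdl, wf, a, p1 = 0.01 * 133.322)
  expect_equal(r$decomposition_particle$mean_flow_speed,
               r$decomposition$mean_flow_speed, tolerance = 0.05)
})

test_that("quasi-1D reduction matches the transient ALE solver on the annulus", {
  props <- fluid_properties()
  R1 <- 30e-6; R2 <- 70e-6; L <- 5e-3; f <- 8.67
  wfm <- synth_pulse_waveform(f)
  mdl <- short_domain_model("annulus", phi_sas = 0.368, L = L)
  a <- 0.05e-6
  q1 <- run_short_domain(mdl, wfm, a, p1 = 0)
  mesh <- mesh_annulus(annulus_domain(R1, R2, L, "traction"),
                       nr = 4L, nz = 25L)
  zin <- mesh$y[mesh_boundary_nodes(mesh, "inner")]
  zout <- mesh$y[mesh_boundary_nodes(mesh, "outer")]
  motion <- function(t) list(
    disp = list(inner = list(ux = a * wfm$an(t - zin), uy = 0),
                outer = list(ux = 0.368 * a * wfm$an(t - zout), uy = 0)),
    vel = list(inner = list(ux = a * wfm$dan(t - zin), uy = 0),
               outer = list(ux = 0.368 * a * wfm$dan(t - zout), uy = 0)))
  run <- run_transient(mesh, props, motion,
                       bc = list(end = "traction", p1 = 0, p2 = 0), f = f,
                       n_cycles = 0.35, steps_per_cycle = 1000L,
                       probes = list(x = (R1 + R2) / 2, z = 4e-3),
                       record_phases = 10L, ptol = 1)
  pr <- run$probe
  sel <- pr$t > 0.1 / f  # drop the short viscous lock-in from rest
  vq <- stats::approx(q1$probe$t, q1$probe$v, xout = pr$t[sel])$y
  amp <- diff(range(vq))
  expect_lt(max(abs(pr$uz[sel] - vq)) / amp, 0.05)
})
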