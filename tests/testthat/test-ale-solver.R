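test_that("fluid properties and anisotropic scaling validate and round-trip", {
  expect_error(fluid_properties(mu_f = 0), "mu_f")
  expect_error(fluid_properties(rho_f = -1), "rho_f")
  expect_error(scaling_spec(0), "L0")
  # g3 from the one-wavelength domain: lambda/(10 R1) ~ 385 (of order 400)
  ss <- scaling_spec(30e-6, domain_length = 1 / 8.67)
  expect_equal(ss$g3, (1 / 8.67) / (10 * 30e-6), tolerance = 1e-12)
  expect_equal(ss$g3, 384.5, tolerance = 1e-3)
  # identity mapping
  id <- scaling_spec(1, g3 = 1)
  p <- list(x = c(1, 2), y = c(3, 4))
  expect_identical(nondimensionalize(p, id), p)
  # round-trip is the identity to machine precision
  mesh <- mesh_annulus(annulus_domain(30e-6, 70e-6, 1 / 8.67), m = 1L)
  m2 <- redimensionalize(nondimensionalize(mesh, ss), ss)
  expect_equal(m2$xg, mesh$xg, tolerance = 1e-14)
  expect_equal(m2$yg, mesh$yg, tolerance = 1e-14)
  # non-dimensional axial length is 10
  nd <- nondimensionalize(mesh, ss)
  expect_equal(diff(range(nd$yg)), 10, tolerance = 1e-12)
})

test_that("gradient anisotropy collapses from ~3 orders to ~1 after scaling", {
  sol <- cached_wave_solution(0.004, m = 1L)
  ss <- scaling_spec(30e-6, domain_length = sol$spec$lambda)
  ga <- gradient_anisotropy(sol$mesh, sol$uz_lab, ss)
  expect_gt(ga$ratio_mesh, 300)      # gradients overwhelmingly radial
  expect_lt(ga$ratio_computational, 10)
  expect_gt(ga$ratio_computational, 0.1)
})

test_that("mesh motion is a harmonic extension with exact boundary match", {
  dom <- annulus_domain(30e-6, 70e-6, 1 / 8.67, "periodic")
  mesh <- mesh_annulus(dom, nr = 6L, nz = 40L)
  cache <- mesh_motion_operator(mesh)
  # zero boundary displacement -> identically zero field
  z0 <- solve_mesh_motion(mesh, list(inner = list(ux = 0, uy = 0),
                                     outer = list(ux = 0, uy = 0)), cache)
  expect_true(all(z0$ux == 0) && all(z0$uy == 0))
  # uniform displacement on both walls -> uniform interior (constants are
  # harmonic)
  d <- 1e-6
  zu <- solve_mesh_motion(mesh, list(inner = list(ux = d, uy = 0),
                                     outer = list(ux = d, uy = 0)), cache)
  expect_equal(zu$ux, rep(d, mesh$n2), tolerance = 1e-12)
  # sinusoidal inner-wall displacement, fixed outer wall: matches the
  # separable harmonic solution sin(k z) sinh(k (R2 - r)) / sinh(k gap)
  k <- 2 * pi / dom$L
  zin <- mesh$y[mesh_boundary_nodes(mesh, "inner")]
  zs <- solve_mesh_motion(mesh,
                          list(inner = list(ux = 1e-7 * sin(k * zin), uy = 0),
                               outer = list(ux = 0, uy = 0)), cache)
  exact <- 1e-7 * sin(k * mesh$y) *
    sinh(k * (70e-6 - mesh$x)) / sinh(k * 40e-6)
  expect_equal(zs$ux, exact, tolerance = 1e-3)
})

test_that("transient solver: zero forcing stays identically zero", {
  mesh <- mesh_channel(40e-6, 40e-6, nr = 4L, nz = 2L, periodic = TRUE)
  run <- run_transient(mesh, fluid_properties(), motion = NULL,
                       bc = list(end = "periodic"), f = 8.67,
                       n_cycles = 0.02, steps_per_cycle = 500L,
                       record_phases = 10L)
  expect_true(all(vapply(run$states, function(s)
    max(abs(s$ux), abs(s$uy)) == 0, TRUE)))
})

test_that("oscillatory channel flow matches the analytic Womersley solution", {
  props <- fluid_properties()
  h <- 40e-6; nu <- props$mu_f / props$rho_f
  for (alpha in c(0.147, 3)) {   # cardiac regime and strongly unsteady
    om <- (2 * alpha / h)^2 * nu
    f <- om / (2 * pi); G0 <- 100
    gam <- sqrt(1i * om / nu)
    uhat <- function(y) (G0 / (1i * om * props$rho_f)) *
      (1 - cosh(gam * (y - h / 2)) / cosh(gam * h / 2))
    mesh <- mesh_channel(h, h, nr = 8L, nz = 2L, periodic = TRUE)
    run <- run_transient(mesh, props, motion = NULL,
                         bc = list(end = "periodic"), f = f,
                         n_cycles = 1, steps_per_cycle = 400L,
                         body = function(t) c(0, G0 * cos(om * t)),
                         probes = list(x = c(h / 2, h / 4), z = rep(h / 2, 2)),
                         init = list(ux = numeric(mesh$n2),
                                     uy = Re(uhat(mesh$x))),
                         record_phases = 4L, ptol = 1e-3)
    umax <- Mod(uhat(h / 2))
    for (k in 1:2) {
      d <- run$probe[run$probe$probe == k, ]
      ua <- Re(uhat(c(h / 2, h / 4)[k]) * exp(1i * om * d$t))
      expect_lt(max(abs(d$uz - ua)) / umax, 0.01,
                label = sprintf("Womersley alpha=%.3g probe %d", alpha, k))
    }
  }
})

test_that("moving-wall ALE conserves volume: end outflux balances dV/dt", {
  props <- fluid_properties()
  mesh <- mesh_annulus(annulus_domain(30e-6, 70e-6, 2e-4, "traction"),
                       nr = 4L, nz = 10L)
  aamp <- 0.3e-6; om <- 2 * pi * 8.67
  motion <- function(t) list(
    disp = list(inner = list(ux = aamp * sin(om * t), uy = 0),
                outer = list(ux = 0, uy = 0)),
    vel = list(inner = list(ux = aamp * om * cos(om * t), uy = 0),
               outer = list(ux = 0, uy = 0)))
  run <- run_transient(mesh, props, motion,
                       bc = list(end = "traction", p1 = 0, p2 = 0),
                       f = 8.67, n_cycles = 0.01, steps_per_cycle = 1000L,
                       record_phases = 1000L, ptol = 1)
  st <- run$state
  dVdt <- sum(vapply(c("inner", "outer", "endA", "endB"), function(s)
    boundary_flux(st$mesh, st$wx, st$wy, s), 0))
  ends <- sum(vapply(c("endA", "endB"), function(s)
    boundary_flux(st$mesh, st$ux, st$uy, s), 0))
  peak <- abs(boundary_flux(st$mesh, st$wx, st$wy, "inner"))
  expect_lt(abs(ends + dVdt) / peak, 1e-8)
  # and the wall flux of the fluid equals the wall-swept rate identically
  walls <- sum(vapply(c("inner", "outer"), function(s)
    boundary_flux(st$mesh, st$ux, st$uy, s), 0))
  expect_equal(walls, dVdt, tolerance = 1e-10)
})

test_that("transient ALE reproduces the traveling-wave solution; Re << 1 so convection is negligible", {
  props <- fluid_properties()
  spec <- wave_spec(0.004)
  R1 <- 30e-6; R2 <- 70e-6; lam <- spec$lambda
  nr <- 4L; nz <- 24L
  wfs <- solve_traveling_wave(spec, R1, R2, props, nr = nr, nz = nz)
  fld <- wave_frame_field(wfs)
  mesh <- mesh_annulus(annulus_domain(R1, R2, lam, "periodic"),
                       nr = nr, nz = nz)
  zin <- mesh$y[mesh_boundary_nodes(mesh, "inner")]
  motion <- function(t) {
    d <- sinusoidal_displacement(spec, R1, zin, t)
    v <- sinusoidal_wall_velocity(spec, R1, zin, t)
    list(disp = list(inner = list(ux = d$ur, uy = 0),
                     outer = list(ux = 0, uy = 0)),
         vel = list(inner = list(ux = v$vr, uy = 0),
                    outer = list(ux = 0, uy = 0)))
  }
  # start from the wave-frame solution evaluated at the deformed t=0 nodes
  mmc <- mesh_motion_operator(mesh)
  d0 <- solve_mesh_motion(mesh, motion(0)$disp, mmc)
  v0 <- fld(mesh$x + d0$ux, mesh$y + d0$uy, 0)
  probes <- list(x = (R1 + R2) / 2, z = lam / 2)
  run <- run_transient(mesh, props, motion, bc = list(end = "periodic"),
                       f = spec$f, n_cycles = 0.12, steps_per_cycle = 1000L,
                       probes = probes, init = list(ux = v0$ur, uy = v0$uz),
                       record_phases = 10L, ptol = 1)
  pr <- run$probe
  ref <- vapply(pr$t, function(t) fld((R1 + R2) / 2, lam / 2, t)$uz, 0)
  amp <- diff(range(ref))
  expect_lt(max(abs(pr$uz - ref)) / amp, 0.05)
  # dropping the convective term barely changes the solution (Re << 1)
  run0 <- run_transient(mesh, props, motion, bc = list(end = "periodic"),
                        f = spec$f, n_cycles = 0.06, steps_per_cycle = 1000L,
                        probes = probes, init = list(ux = v0$ur, uy = v0$uz),
                        include_convection = FALSE,
                        record_phases = 10L, ptol = 1)
  n <- nrow(run0$probe)
  expect_lt(max(abs(run0$probe$uz - pr$uz[seq_len(n)])) / amp, 0.02)
})
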