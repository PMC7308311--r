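test_that("annular resistance: closed form, limits and monotonicity", {
  mu <- 1e-3
  # circular-pipe limit r1 -> 0 (the log correction vanishes slowly, so the
  # exact r1 = 0 branch is provided; small r1 approaches it from above)
  expect_equal(annular_resistance(0, 70e-6, mu), 8 * mu / (pi * 70e-6^4))
  expect_equal(annular_resistance(1e-12, 70e-6, mu),
               8 * mu / (pi * 70e-6^4), tolerance = 0.1)
  expect_lt(abs(annular_resistance(1e-12, 70e-6, mu) /
                  (8 * mu / (pi * 70e-6^4)) - 1),
            abs(annular_resistance(1e-6, 70e-6, mu) /
                  (8 * mu / (pi * 70e-6^4)) - 1))
  # gap closing: resistance diverges
  expect_gt(annular_resistance(69.99e-6, 70e-6, mu),
            1e6 * annular_resistance(30e-6, 70e-6, mu))
  # strictly increasing in r1, decreasing in r2
  r1s <- seq(10e-6, 60e-6, by = 10e-6)
  expect_true(all(diff(annular_resistance(r1s, 70e-6, mu)) > 0))
  r2s <- seq(40e-6, 90e-6, by = 10e-6)
  expect_true(all(diff(annular_resistance(30e-6, r2s, mu)) < 0))
  expect_error(annular_resistance(70e-6, 30e-6, mu), "smaller")
  expect_error(annular_resistance(30e-6, 70e-6, 0), "mu")
})

test_that("numeric annulus Poiseuille matches the closed form across radius ratios", {
  mu <- 1e-3; r2 <- 70e-6
  for (ratio in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    r1 <- ratio * r2
    dom <- annulus_domain(r1, r2, 1e-4, "periodic")
    mesh <- mesh_annulus(dom, nr = 8L, nz = 4L)
    ps <- solve_section_poiseuille(mesh, mu, dpdz = -100)
    expect_equal(ps$Q, 100 / annular_resistance(r1, r2, mu),
                 tolerance = 5e-3,
                 label = sprintf("Q at r1/r2 = %.1f", ratio))
  }
})

test_that("steady Stokes solver reproduces the annular profile", {
  mu <- 1e-3
  dom <- annulus_domain(30e-6, 70e-6, 1e-4, "periodic")
  mesh <- mesh_annulus(dom, nr = 10L, nz = 4L)
  G <- 266.64  # favourable gradient magnitude, Pa/m
  st <- solve_flow_steady(mesh, mu, rho = 0,
                          dirichlet = list(inner = list(ux = 0, uy = 0),
                                           outer = list(ux = 0, uy = 0)),
                          body = c(0, G))
  wex <- annulus_profile_exact(30e-6, 70e-6, mu, -G)
  rs <- seq(32e-6, 68e-6, length.out = 7)
  uz <- fem_eval_points(mesh, st$uy, rs, rep(5e-5, 7))
  expect_equal(uz, wex(rs), tolerance = 5e-3)
  # discrete incompressibility and the zero-mean pressure gauge
  expect_lt(divergence_residual(mesh, st$ux, st$uy), 1e-8)
  ops <- assemble_stokes(mesh, mu)
  # integral of p over the domain vanishes (p itself is ~0 for body-force
  # driven Poiseuille flow, so compare against the viscous pressure scale)
  pscale <- mu * max(abs(st$uy)) / (40e-6)
  expect_lt(abs(sum(ops$gp * st$p)) / (mesh_volume(mesh) * pscale), 1e-8)
})

test_that("section solver: linearity, scale invariance, degenerate input", {
  built <- build_lobed_section(30e-6, target_edge_length = 3e-6)
  mu <- 1e-3
  s1 <- solve_section_poiseuille(built$mesh, mu, dpdz = -100)
  s2 <- solve_section_poiseuille(built$mesh, mu, dpdz = -200)
  expect_equal(s2$Q, 2 * s1$Q, tolerance = 1e-12)
  expect_equal(s2$w, 2 * s1$w, tolerance = 1e-12)
  s0 <- solve_section_poiseuille(built$mesh, mu, dpdz = 0)
  expect_true(all(s0$w == 0)); expect_equal(s0$Q, 0)
  # scaling all lengths by s multiplies Q by s^4 at fixed dpdz
  sc <- 2
  builtS <- build_lobed_section(30e-6 * sc, target_edge_length = 3e-6 * sc)
  sS <- solve_section_poiseuille(builtS$mesh, mu, dpdz = -100)
  expect_equal(sS$Q, sc^4 * s1$Q, tolerance = 1e-6)
})

test_that("lobed-section solution is refinement-converged", {
  lp1 <- lobed_poiseuille(build_lobed_section(30e-6, target_edge_length = 2e-6),
                          1e-3, dp = 0.01 * 133.322, L = 5e-3)
  lp2 <- lobed_poiseuille(build_lobed_section(30e-6, target_edge_length = 1e-6),
                          1e-3, dp = 0.01 * 133.322, L = 5e-3)
  expect_equal(lp1$v_mid, lp2$v_mid, tolerance = 5e-3)
  expect_equal(lp1$Q, lp2$Q, tolerance = 5e-3)
})

test_that("Re/Pe pipe-flow metrics follow the stated formulas", {
  # annulus: D_h = 2 (r2 - r1)
  r1 <- 30e-6; r2 <- 70e-6
  A <- pi * (r2^2 - r1^2); P <- 2 * pi * (r1 + r2)
  met <- compute_re_pe(Q = 1e-12, v_ave = 24.4e-6, area = A, perimeter = P)
  expect_equal(met$D_h, 2 * (r2 - r1))
  expect_equal(met$Re, 1000 * 1e-12 * met$D_h / (1e-3 * A))
  # Pe with the amyloid-beta diffusivity 1.4e-6 cm^2/s = 1.4e-10 m^2/s
  expect_equal(met$Pe, 24.4e-6 * met$D_h / 1.4e-10)
  expect_error(compute_re_pe(1, 1, area = 1, perimeter = 0), "perimeter")
})
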