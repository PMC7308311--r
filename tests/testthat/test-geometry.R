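test_that("annulus domains validate inputs and mesh at the stated resolutions", {
  expect_error(annulus_domain(70e-6, 30e-6, 1), "R1 must be smaller")
  expect_error(annulus_domain(-1e-6, 30e-6, 1), "R1 must be positive")
  expect_error(annulus_domain(30e-6, 70e-6, 0), "L must be positive")
  expect_error(build_annulus(30e-6, 70e-6, 1e-3, m = 0.5), "m must be")

  lam <- 1 / 8.67
  b2 <- build_annulus(30e-6, 70e-6, lam, "periodic", m = 2L)
  expect_equal(c(b2$mesh$nr, b2$mesh$nz), c(10L, 100L))
  b1 <- build_annulus(30e-6, 70e-6, 5e-3, "traction", m = 1L)
  expect_equal(c(b1$mesh$nr, b1$mesh$nz), c(5L, 50L))
  # refinement consistency: x4 elements per doubling of m
  expect_identical(b2$mesh$ne, 4L * b1$mesh$ne)

  # meshed volume matches the analytic annular volume
  expect_equal(mesh_volume(b2$mesh), pi * (70e-6^2 - 30e-6^2) * lam,
               tolerance = 1e-12)

  # grading: element-size ratio between largest and smallest radial
  # elements stays at/below 3
  r <- b2$mesh$x[seq_len(b2$mesh$Ni)]
  dr <- diff(r[seq(1, length(r), by = 2)])
  expect_lt(max(dr) / min(dr), 3 + 1e-6)
})

test_that("lobed section geometry: intersections, fillets, mirror symmetry", {
  expect_error(lobed_cross_section(30e-6, b_out = 40e-6),
                "b_out must be smaller")
  expect_error(lobed_cross_section(30e-6, a_out = 20e-6), "a_out must exceed")
  expect_error(lobed_cross_section(30e-6, fillet_r = 20e-6), "fillet")

  sec <- lobed_cross_section(30e-6)
  # corner lies on both curves
  expect_equal(sqrt(sum(sec$corner^2)), 30e-6, tolerance = 1e-12)
  expect_equal((sec$corner[1] / sec$a_out)^2 + (sec$corner[2] / sec$b_out)^2,
               1, tolerance = 1e-10)
  # fillet tangency: tangency points sit on their curves at distance
  # fillet_r from the fillet center
  expect_equal(sqrt(sum((sec$tangent_circle - sec$fillet_center)^2)),
               sec$fillet_r, tolerance = 1e-9 * sec$fillet_r + 1e-18)
  expect_equal(sqrt(sum((sec$tangent_ellipse - sec$fillet_center)^2)),
               sec$fillet_r, tolerance = 1e-6 * sec$fillet_r)
  # C1 junction: fillet arc tangent matches circle tangent at the circle
  # tangency point (radial alignment implies tangential continuity)
  rad_c <- sec$tangent_circle / sqrt(sum(sec$tangent_circle^2))
  rad_f <- (sec$tangent_circle - sec$fillet_center) / sec$fillet_r
  expect_equal(abs(sum(rad_c * rad_f)), 1, tolerance = 1e-8)

  built <- build_lobed_section(30e-6, target_edge_length = 2e-6)
  # mirror symmetry of the meshed lobe across the major axis
  ids <- mesh_boundary_nodes(built$mesh, "inner")
  xy <- cbind(built$mesh$x[ids], built$mesh$y[ids])
  refl <- xy %*% diag(c(1, -1))
  d <- vapply(seq_len(nrow(refl)), function(i)
    min(sqrt(colSums((t(xy) - refl[i, ])^2))), 0)
  expect_lt(max(d), 1e-9)
})

test_that("meshed lobe area matches the closed-form circle/ellipse area", {
  built0 <- build_lobed_section(30e-6, fillet_r = 0, target_edge_length = 2e-6)
  expect_equal(mesh_volume(built0$mesh), lobe_area_analytic(built0$section),
               tolerance = 5e-3)
  # with the standard fillet the area is slightly smaller (corners shaved)
  built <- build_lobed_section(30e-6, target_edge_length = 2e-6)
  expect_lt(mesh_volume(built$mesh), lobe_area_analytic(built$section))
  expect_gt(mesh_volume(built$mesh), 0.98 * lobe_area_analytic(built$section))
})

test_that("mid-gap probe points follow the (R1+R2)/2 rule", {
  dom <- annulus_domain(30e-6, 70e-6, 1e-3)
  expect_equal(point_midgap(dom)$r, 50e-6)
  sec <- lobed_cross_section(30e-6)
  pm <- point_midgap(sec)
  expect_equal(c(pm$x, pm$y), c(50e-6, 0))
  # the probe lies inside the meshed lobe: field evaluation succeeds
  built <- build_lobed_section(30e-6, target_edge_length = 2e-6)
  v <- fem_eval_points(built$mesh, rep(1, built$mesh$n2), pm$x, pm$y)
  expect_equal(as.numeric(v), 1, tolerance = 1e-10)
})
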