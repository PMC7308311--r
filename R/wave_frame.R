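# Steady traveling-wave formulation of the periodic peristalsis problem.
#
# For the one-wavelength annulus with periodic ends and a sinusoidal
# traveling wall wave, the time-periodic solution of the lab-frame ALE
# problem is an exact traveling wave: in the frame moving with the wave
# speed c the domain shape is frozen (inner radius r1(xi) = R1 (1 + phi0
# sin(k xi)), xi = z - c t) and the flow is steady.  Solving the steady
# Navier-Stokes equations in that frame with wall velocities
#   inner: (v_r, v_z) = (d u_mr / dt, -c)   (tangent to the frozen wall)
#   outer: (0, -c)
# and recovering lab-frame fields via v_lab = v_wave + c e_z reproduces the
# full cycle-periodic solution at the cost of one steady solve.  The
# transient ALE solver (run_transient) is the general path; this route is
# used for the one-wavelength production runs and is cross-checked against
# the transient solver in the test suite.

#' Deformed periodic annulus mesh in the wave frame
#'
#' @param spec a [wave_spec()].
#' @param R1,R2 baseline radii, m.
#' @param m refinement factor (`5*m` radial x `50*m` axial elements).
#' @param nr,nz optional explicit element counts.
#' @return a `quad_mesh` whose inner boundary follows
#'   `r1(xi) = R1 * (1 + phi0 * sin(2*pi*xi/lambda))`.
#' @keywords internal
mesh_wave_frame <- function(spec, R1, R2, m = 2L, nr = NULL, nz = NULL) {
  if (is.null(nr)) nr <- 5L * as.integer(m)
  if (is.null(nz)) nz <- 50L * as.integer(m)
  Ni <- 2L * nr + 1L; Njg <- 2L * nz + 1L
  lam <- spec$lambda
  xi <- seq(0, 1, length.out = Njg) * lam
  r_in <- R1 * (1 + spec$phi0 * sin(2 * pi * xi / lam))
  s <- .grade_both(seq(0, 1, length.out = Ni))
  X <- outer(s, r_in, function(sv, ri) ri + (R2 - ri) * sv)
  Y <- matrix(xi, Ni, Njg, byrow = TRUE)
  quad_mesh(X, Y, nr, nz, periodic = TRUE, axisym = TRUE)
}

#' Solve the periodic peristalsis problem in the traveling-wave frame
#'
#' @param spec a [wave_spec()].
#' @param R1,R2 annulus radii, m.
#' @param props a [fluid_properties()] (viscosity, density).
#' @param m refinement factor (production resolution `m = 2`).
#' @param nr,nz optional explicit element counts.
#' @param picard,tol Picard controls for the convective term.
#' @param reverse solve with the wave traveling in -z (c -> -c).
#' @return a `wave_frame_solution`: the deformed mesh, wave-frame nodal
#'   fields `ux` (radial), `uy` (axial), `p`, lab-frame axial velocity
#'   `uz_lab = uy + c`, and the run description.
#' @export
solve_traveling_wave <- function(spec, R1 = 30e-6, R2 = 70e-6,
                                 props = fluid_properties(),
                                 m = 2L, nr = NULL, nz = NULL,
                                 picard = 6L, tol = 1e-9, reverse = FALSE) {
  stopifnot(inherits(spec, "peristaltic_wave"))
  # With displacement u_mr = phi0 R1 sin(k (z - c t)) the wave coordinate is
  # xi = z - c t for either wave direction, and the frozen shape
  # r1(xi) = R1 (1 + phi0 sin(k xi)) is the same; only the wall velocity
  # -phi0 R1 k c cos(k xi) changes sign with c.
  cs <- if (reverse) -spec$c else spec$c
  mesh <- mesh_wave_frame(spec, R1, R2, m = m, nr = nr, nz = nz)
  lam <- spec$lambda; k <- 2 * pi / lam
  ids_in <- mesh_boundary_nodes(mesh, "inner")
  xi_in <- mesh$y[ids_in]
  ur_in <- -spec$phi0 * R1 * k * cs * cos(k * xi_in)
  sol <- solve_flow_steady(
    mesh, mu = props$mu_f, rho = props$rho_f,
    dirichlet = list(inner = list(ux = ur_in, uy = -cs),
                     outer = list(ux = 0, uy = -cs)),
    traction = NULL, picard = picard, tol = tol)
  structure(list(
    mesh = mesh, spec = spec, R1 = R1, R2 = R2, props = props,
    c = cs, reverse = reverse,
    ux = sol$ux, uy = sol$uy, p = sol$p,
    uz_lab = sol$uy + cs, ur_lab = sol$ux,
    iters = sol$iters, delta = sol$delta
  ), class = "wave_frame_solution")
}

#' @export
print.wave_frame_solution <- function(x, ...) {
  cat(sprintf(
    "<wave_frame_solution> phi0 = %.4g, c = %g m/s, f = %g Hz, mesh %d x %d\n",
    x$spec$phi0, x$c, x$spec$f, x$mesh$nr, x$mesh$nz))
  invisible(x)
}

# invert the radial grading: logical s such that r(s) = r0 on column xi
.wave_frame_s_of_r <- function(sol, r0, xi) {
  lam <- sol$spec$lambda
  r_in <- sol$R1 * (1 + sol$spec$phi0 * sin(2 * pi * xi / lam))
  frac <- (r0 - r_in) / (sol$R2 - r_in)
  vapply(frac, function(fr) {
    if (fr <= 0) return(0)
    if (fr >= 1) return(1)
    stats::uniroot(function(s) .grade_both(s) - fr, c(0, 1), tol = 1e-14)$root
  }, 0)
}

#' Lab-frame probe series from a wave-frame solution
#'
#' Evaluates the lab-frame fluid velocity at a fixed lab point `(r0, z)`
#' over times `t`: the material seen at that point corresponds to wave
#' coordinate `xi = z - c t` (mod lambda).
#'
#' @param sol a `wave_frame_solution`.
#' @param r0 radial probe position, m (default mid-gap).
#' @param z axial lab position, m (default `lambda/2`).
#' @param times evaluation times, s.
#' @return data.frame with `t`, `xi`, `uz` (lab axial velocity), `ur`,
#'   `p`, and the inner-wall radial velocity `wall_vr` at the same `z`.
#' @export
wave_frame_probe <- function(sol, r0 = (sol$R1 + sol$R2) / 2,
                             z = sol$spec$lambda / 2,
                             times = seq(0, 1 / sol$spec$f,
                                         length.out = 201L)) {
  lam <- sol$spec$lambda
  xi <- (z - sol$c * times) %% lam
  s <- .wave_frame_s_of_r(sol, r0, xi)
  tl <- xi / lam
  uz <- fem_eval_logical(sol$mesh, sol$uz_lab, s, tl)
  ur <- fem_eval_logical(sol$mesh, sol$ur_lab, s, tl)
  p <- fem_eval_logical(sol$mesh, sol$p, s, tl)
  # wall radial velocity at the same z for the (signed) wave speed c:
  # u_mr = phi0 R1 sin(k (z - c t))  =>  vr = -phi0 R1 k c cos(k (z - c t))
  k <- 2 * pi / lam
  wall_vr <- -sol$spec$phi0 * sol$R1 * k * sol$c * cos(k * (z - sol$c * times))
  data.frame(t = times, xi = xi, uz = uz, ur = ur, p = p, wall_vr = wall_vr)
}

#' Lab-frame velocity field function from a wave-frame solution
#'
#' Returns `function(x, z, t)` giving the lab-frame velocity components
#' `(ur, uz)` at radius `x`, axial position `z`, time `t` — suitable for
#' particle advection.
#'
#' @param sol a `wave_frame_solution`.
#' @export
wave_frame_field <- function(sol) {
  lam <- sol$spec$lambda
  function(x, z, t) {
    xi <- (z - sol$c * t) %% lam
    s <- .wave_frame_s_of_r(sol, x, xi)
    tl <- xi / lam
    list(ur = fem_eval_logical(sol$mesh, sol$ur_lab, s, tl),
         uz = fem_eval_logical(sol$mesh, sol$uz_lab, s, tl))
  }
}

#' Cycle metrics of the periodic peristalsis solution
#'
#' Computes, at the mid-gap centerline, the Eulerian cycle-mean lab axial
#' velocity, the Lagrangian mean flow speed (net particle drift per cycle
#' times f, from pathline integration in the steady wave-frame field), the
#' oscillatory (peak-to-peak) axial velocity, their ratio and the
#' wall-to-fluid phase difference.
#'
#' @param sol a `wave_frame_solution`.
#' @param nsample samples per cycle.
#' @return list of metrics (m/s and degrees).
#' @export
wave_frame_metrics <- function(sol, nsample = 400L) {
  r0 <- (sol$R1 + sol$R2) / 2
  Tp <- 1 / sol$spec$f
  pr <- wave_frame_probe(sol, r0 = r0,
                         times = (seq_len(nsample) - 1) / nsample * Tp)
  mean_eul <- mean(pr$uz)
  osc <- diff(range(pr$uz))
  # Lagrangian drift: in the wave frame the flow is steady, so integrate the
  # pathline through (r0, xi=0) until it crosses one wavelength
  drift <- .wave_frame_drift(sol, r0)
  phase <- phase_difference(pr$wall_vr, pr$uz, sol$spec$f, pr$t)
  list(mean_eulerian = mean_eul,
       mean_lagrangian = drift$mean_speed,
       oscillatory = osc,
       ratio_eulerian = abs(mean_eul) / osc,
       ratio_lagrangian = abs(drift$mean_speed) / osc,
       phase_deg = phase,
       probe = pr)
}

# integrate the steady wave-frame pathline through (r0, xi0) across one
# wavelength; returns the lab drift per period and mean speed
.wave_frame_drift <- function(sol, r0, xi0 = 0, nstep = 4000L) {
  lam <- sol$spec$lambda
  vf <- function(r, xi) {
    s <- .wave_frame_s_of_r(sol, r, xi %% lam)
    tl <- (xi %% lam) / lam
    c(fem_eval_logical(sol$mesh, sol$ux, s, tl),
      fem_eval_logical(sol$mesh, sol$uy, s, tl))
  }
  # march in xi (the axial wave coordinate decreases at rate ~ -c)
  state <- c(r0, xi0)
  ttot <- 0
  dxi <- -lam / nstep * sign(sol$c)
  for (i in seq_len(nstep)) {
    # RK4 in xi with dt = dxi / uz_wave
    f1 <- vf(state[1], state[2]); k1 <- c(f1[1] / f1[2], 1 / f1[2])
    f2 <- vf(state[1] + 0.5 * dxi * k1[1], state[2] + 0.5 * dxi)
    k2 <- c(f2[1] / f2[2], 1 / f2[2])
    f3 <- vf(state[1] + 0.5 * dxi * k2[1], state[2] + 0.5 * dxi)
    k3 <- c(f3[1] / f3[2], 1 / f3[2])
    f4 <- vf(state[1] + dxi * k3[1], state[2] + dxi)
    k4 <- c(f4[1] / f4[2], 1 / f4[2])
    state[1] <- state[1] + dxi / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    state[2] <- state[2] + dxi
    ttot <- ttot + dxi / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  }
  # after traversing one wavelength in the wave frame (time ttot), the lab
  # displacement is c * ttot - lambda (for a +z wave)
  dz <- sol$c * ttot - sign(sol$c) * lam
  list(period = ttot, drift = dz, mean_speed = dz / ttot)
}
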