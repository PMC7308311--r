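# Scripted computational experiments: the amplitude sweep on the periodic
# one-wavelength annulus, the short-domain pressure sweep, the mesh
# convergence ladder, the 2D channel peristalsis demonstration, and the
# steady pressure sweep through the lobed section.  Each driver returns
# tidy tables plus an echo of its full configuration; `write_run_outputs()`
# serialises them (YAML config + CSV tables) for the analysis scripts.

.grade_both_deriv <- function(s, beta = 0.5) 1 - beta * cos(2 * pi * s)

#' Lab-frame volumetric flux at a wave station
#'
#' Integrates the lab axial velocity over the annular cross-section at wave
#' coordinate `xi` (radial Gauss-Legendre in the graded logical coordinate).
#'
#' @param sol a `wave_frame_solution`.
#' @param xi wave coordinate(s), m.
#' @param nq radial quadrature points.
#' @return flux in m^3/s, one value per `xi`.
#' @export
wave_frame_flux <- function(sol, xi, nq = 32L) {
  lam <- sol$spec$lambda
  # composite Simpson on the logical radial coordinate is ample at nq ~ 33
  ns <- if (nq %% 2 == 0) nq + 1L else nq
  s <- seq(0, 1, length.out = ns)
  ds <- 1 / (ns - 1)
  simp <- c(1, rep(c(4, 2), length.out = ns - 2), 1)
  vapply(xi, function(x) {
    r_in <- sol$R1 * (1 + sol$spec$phi0 * sin(2 * pi * x / lam))
    r <- r_in + (sol$R2 - r_in) * .grade_both(s)
    dr <- (sol$R2 - r_in) * .grade_both_deriv(s)
    uz <- fem_eval_logical(sol$mesh, sol$uz_lab, s, (x %% lam) / lam)
    sum(simp * uz * 2 * pi * r * dr) * ds / 3
  }, 0)
}

#' Amplitude sweep of the periodic peristalsis model
#'
#' For each half-wave amplitude `phi0`, solves the one-wavelength annulus
#' (periodic ends, Table-parameter defaults) and reports the centerline
#' flow decomposition, phase and Reynolds number.
#'
#' @param phi0s half-wave amplitude fractions (see
#'   [amp_from_pp_radius_pct()]).
#' @param m mesh refinement factor.
#' @param R1,R2 annulus radii, m.
#' @param c,f wave speed (m/s) and frequency (Hz).
#' @param props [fluid_properties()].
#' @param D diffusion coefficient for the Peclet number, m^2/s.
#' @return a `sweep_table` data.frame, one row per amplitude, sorted by
#'   amplitude, with the configuration in `attr(, "config")`.
#' @export
run_amplitude_sweep <- function(phi0s, m = 2L, R1 = 30e-6, R2 = 70e-6,
                                c = 1, f = 8.67,
                                props = fluid_properties(), D = 1.4e-10) {
  phi0s <- sort(phi0s)
  A <- pi * (R2^2 - R1^2)
  P <- 2 * pi * (R1 + R2)
  D_h <- 4 * A / P
  rows <- lapply(phi0s, function(phi0) {
    if (phi0 == 0) {
      return(data.frame(phi0 = 0, pp_radius_pct = 0, mean_eulerian = 0,
                        mean_lagrangian = 0, oscillatory = 0, ratio = NA,
                        log10_osc_over_mean = NA, phase_deg = NA,
                        Re = 0, Pe = 0, converged = TRUE))
    }
    sol <- solve_traveling_wave(wave_spec(phi0, c, f), R1, R2, props, m = m)
    mets <- wave_frame_metrics(sol)
    Qpk <- max(abs(wave_frame_flux(sol, seq(0, sol$spec$lambda,
                                            length.out = 65L))))
    re <- compute_re_pe(Qpk, mets$mean_eulerian, A, P,
                        rho = props$rho_f, mu = props$mu_f, D = D)
    data.frame(phi0 = phi0, pp_radius_pct = pp_radius_pct_from_amp(phi0),
               mean_eulerian = mets$mean_eulerian,
               mean_lagrangian = mets$mean_lagrangian,
               oscillatory = mets$oscillatory,
               ratio = mets$ratio_eulerian,
               log10_osc_over_mean =
                 log10(mets$oscillatory / abs(mets$mean_eulerian)),
               phase_deg = mets$phase_deg,
               Re = re$Re, Pe = re$Pe,
               converged = sol$delta < 1e-6)
  })
  out <- do.call(rbind, rows)
  if (any(!out$converged))
    warning("non-converged runs at phi0 = ",
            paste(out$phi0[!out$converged], collapse = ", "))
  attr(out, "config") <- list(experiment = "amplitude_sweep", phi0s = phi0s,
                              m = m, R1 = R1, R2 = R2, c = c, f = f,
                              mu_f = props$mu_f, rho_f = props$rho_f, D = D)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Mesh-convergence ladder of the periodic peristalsis model
#'
#' Solves the configuration at successive refinement factors and reports the
#' relative L2 error norms of velocity and pressure between consecutive
#' levels (m vs 2m), integrated over the whole domain.
#'
#' @param m_values refinement factors, e.g. `c(1, 2, 4)`.
#' @param phi0 half-wave amplitude fraction.
#' @inheritParams run_amplitude_sweep
#' @return data.frame with one row per consecutive pair: `m`, `L2Err_v`,
#'   `L2Err_p` (fractions; multiply by 100 for %).
#' @export
run_convergence_study <- function(m_values = c(1L, 2L, 4L), phi0 = 0.004,
                                  R1 = 30e-6, R2 = 70e-6, c = 1, f = 8.67,
                                  props = fluid_properties()) {
  m_values <- sort(unique(as.integer(m_values)))
  spec <- wave_spec(phi0, c, f)
  sols <- lapply(m_values, function(m)
    solve_traveling_wave(spec, R1, R2, props, m = m))
  rows <- lapply(seq_len(length(m_values) - 1L), function(i) {
    if (m_values[i + 1] != 2L * m_values[i])
      stop("m_values must double between consecutive levels")
    e <- l2_error_norms(sols[[i]], sols[[i + 1]])
    data.frame(m = m_values[i], L2Err_v = e$L2Err_v, L2Err_p = e$L2Err_p)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(experiment = "convergence", m_values = m_values,
                              phi0 = phi0, R1 = R1, R2 = R2, c = c, f = f)
  out
}

#' Short-domain pressure sweep
#'
#' The MCA-length PVS with both walls moving (synthetic cardiac waveform,
#' amplitude tuned so the oscillatory mid-gap velocity matches the in-vivo
#' 10-20 um/s range) under applied end-to-end pressure differences.
#'
#' @param p1_mmHg applied pressure differences, mmHg.
#' @param geometry passed to [short_domain_model()].
#' @param waveform a `pulse_waveform` (default: synthetic cardiac at
#'   8.67 Hz).
#' @param phi_sas outer-wall displacement scale.
#' @param target_osc oscillatory-velocity tuning target, m/s.
#' @param probe_z probe position, m.
#' @return a `sweep_table` with one row per pressure, plus the tuned
#'   amplitude and model in attributes; `traces` attribute carries the probe
#'   series of each run.
#' @export
run_short_domain_pressure <- function(p1_mmHg = c(0, 0.005, 0.01, 0.02),
                                      geometry = "lobed",
                                      waveform = NULL, phi_sas = 0.368,
                                      target_osc = 15e-6, probe_z = 4e-3) {
  if (is.null(waveform)) waveform <- synth_pulse_waveform(8.67)
  model <- short_domain_model(geometry, phi_sas = phi_sas)
  a <- tune_short_domain_amplitude(model, waveform, target_osc, probe_z)
  runs <- lapply(p1_mmHg, function(pm)
    run_short_domain(model, waveform, a, p1 = pm * MMHG_PA,
                     probe_z = probe_z))
  rows <- mapply(function(pm, r) {
    data.frame(p1_mmHg = pm,
               mean_flow_speed = r$decomposition$mean_flow_speed,
               mean_particle = r$decomposition_particle$mean_flow_speed,
               oscillatory = r$decomposition$oscillatory_velocity,
               ratio = r$decomposition$ratio,
               phase_deg = r$phase_deg)
  }, p1_mmHg, runs, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(experiment = "short_domain_pressure",
                              p1_mmHg = p1_mmHg, geometry = geometry,
                              phi_sas = phi_sas, amplitude_m = a,
                              target_osc = target_osc, probe_z = probe_z,
                              f = waveform$f, waveform = waveform$shape)
  attr(out, "amplitude") <- a
  attr(out, "model") <- model
  attr(out, "traces") <- lapply(runs, `[[`, "probe")
  class(out) <- c("sweep_table", class(out))
  out
}

#' 2D channel peristalsis demonstration
#'
#' A planar channel with zero traction (open, pressure-free) ends and a
#' constriction moving in +z: the walls squeeze inward at the neck, and the
#' gap on the trailing (retrograde) side is narrower than on the leading
#' (anterograde) side.  The quasi-static Stokes solve shows the pressure
#' maximum at the neck and a larger anterograde than retrograde outflux,
#' the flux split being set by the lubrication resistances `R ~ 1/h^3`.
#'
#' @param h0 undeformed gap, m.
#' @param L channel length, m.
#' @param neck_frac axial position of the neck as a fraction of `L`.
#' @param depth constriction depth as a fraction of `h0`.
#' @param trail_depth additional trailing-side (already passed) constriction
#'   fraction; `0` gives a symmetric neck.
#' @param V wall inward speed at the neck, m/s.
#' @param nr,nz mesh resolution.
#' @param mu viscosity, Pa s.
#' @return list with the mesh, fields, end fluxes `Q_a` (anterograde, out of
#'   the far end) and `Q_r` (retrograde), the lubrication prediction of the
#'   split, and the centerline pressure profile.
#' @export
run_channel_demo <- function(h0 = 1e-4, L = 2e-3, neck_frac = 0.6,
                             depth = 0.25, trail_depth = 0.15, V = 1e-4,
                             nr = 8L, nz = 60L, mu = 1e-3) {
  zc <- neck_frac * L
  sig <- 0.06 * L
  # gap profile: moving neck plus a plateau of residual constriction behind
  gap <- function(z) {
    neck <- depth * exp(-((z - zc) / sig)^2)
    trail <- trail_depth * smoothstep_quintic((zc - z) / (4 * sig)) *
      smoothstep_quintic(z / (4 * sig) )
    h0 * (1 - neck - trail)
  }
  wallspeed <- function(z) V * exp(-((z - zc) / sig)^2)
  mesh0 <- mesh_channel(h0, L, nr = nr, nz = nz, periodic = FALSE)
  # deform symmetric about the centerline
  hz <- gap(mesh0$yg)
  X <- h0 / 2 + (mesh0$xg - h0 / 2) * hz / h0
  mesh <- mesh_set_coords(mesh0, X, mesh0$yg)
  zin <- mesh$y[mesh_boundary_nodes(mesh, "inner")]
  zout <- mesh$y[mesh_boundary_nodes(mesh, "outer")]
  sol <- solve_flow_steady(
    mesh, mu, rho = 0,
    dirichlet = list(inner = list(ux = wallspeed(zin), uy = 0),
                     outer = list(ux = -wallspeed(zout), uy = 0)),
    traction = list(endA = 0, endB = 0))
  Q_r <- boundary_flux(mesh, sol$ux, sol$uy, "endA")
  Q_a <- boundary_flux(mesh, sol$ux, sol$uy, "endB")
  # lubrication: Q(z) = Q0 + int_0^z hdot' ; p(0)=p(L)=0 fixes Q0
  zg <- seq(0, L, length.out = 2001L)
  hdot <- -2 * wallspeed(zg)              # gap closes at 2 V at the neck
  cum <- c(0, cumsum((hdot[-1] + hdot[-length(zg)]) / 2 * diff(zg)))
  h3 <- gap(zg)^3
  # Q(z) = Q0 - cum(z); 0 = int (Q0 - cum)/h^3 -> Q0
  w <- 1 / h3
  Q0 <- sum((cum * w)[-1] * diff(zg)) / sum(w[-1] * diff(zg))
  Q_lub_r <- -Q0                           # outflux at z = 0
  Q_lub_a <- Q0 - cum[length(cum)]         # outflux at z = L
  # centerline pressure profile (columns stay at fixed z: logical eval)
  pz <- seq(0.02 * L, 0.98 * L, length.out = 49L)
  pc <- fem_eval_logical(mesh, sol$p, 0.5, pz / L)
  list(mesh = mesh, ux = sol$ux, uy = sol$uy, p = sol$p,
       Q_a = Q_a, Q_r = Q_r,
       split = Q_a / Q_r, split_lub = Q_lub_a / Q_lub_r,
       pressure_profile = data.frame(z = pz, p = pc),
       gap = gap, wallspeed = wallspeed,
       config = list(experiment = "channel_demo", h0 = h0, L = L,
                     neck_frac = neck_frac, depth = depth,
                     trail_depth = trail_depth, V = V, nr = nr, nz = nz,
                     mu = mu))
}

#' Steady pressure sweep through the lobed section
#'
#' @param dp_mmHg pressure differences over the segment, mmHg.
#' @param L segment length, m.
#' @param R1 arterial radius, m.
#' @param mu,rho fluid properties.
#' @param D diffusion coefficient, m^2/s.
#' @param target_edge_length mesh resolution.
#' @return data.frame with `dp_mmHg`, `dpdz` (Pa/m), `Q` (m^3/s), `v_mid`
#'   (m/s), `Re`, `Pe`.
#' @export
run_steady_section_sweep <- function(dp_mmHg = c(0.001, 0.005, 0.01, 0.02,
                                                 0.05),
                                     L = 5e-3, R1 = 30e-6, mu = 1e-3,
                                     rho = 1000, D = 1.4e-10,
                                     target_edge_length = 2e-6) {
  built <- build_lobed_section(R1, target_edge_length = target_edge_length)
  rows <- lapply(dp_mmHg, function(dp) {
    lp <- lobed_poiseuille(built, mu, dp = dp * MMHG_PA, L = L)
    met <- compute_re_pe(lp$Q, lp$v_mid, lp$area, lp$perimeter,
                         rho = rho, mu = mu, D = D)
    data.frame(dp_mmHg = dp, dpdz = -dp * MMHG_PA / L, Q = lp$Q,
               v_mid = lp$v_mid, Re = met$Re, Pe = met$Pe)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(experiment = "steady_section_sweep",
                              dp_mmHg = dp_mmHg, L = L, R1 = R1, mu = mu,
                              rho = rho, D = D,
                              target_edge_length = target_edge_length)
  out
}

#' Write experiment outputs (config echo + CSV tables)
#'
#' @param dir output directory (created if needed).
#' @param name run name (file prefix).
#' @param tables named list of data.frames.
#' @param config configuration list (echoed as YAML and JSON).
#' @return the directory, invisibly.
#' @export
write_run_outputs <- function(dir, name, tables = list(), config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (length(config)) {
    yaml::write_yaml(config, file.path(dir, paste0(name, "_config.yaml")))
    jsonlite::write_json(config, file.path(dir, paste0(name, "_config.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]],
                     file.path(dir, paste0(name, "_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
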