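# Short-domain PVS model: the MCA-length (5 mm) segment, which is far
# shorter than the pulse wavelength (~115 mm), so the walls move essentially
# in phase along the whole segment ("in and out simultaneously").  In this
# long-wavelength limit the flow is quasi-one-dimensional: wall motion
# drives a squeeze flux through mass conservation, a steady end-to-end
# pressure difference drives a superposed Poiseuille flow, and the local
# profile is the fully developed section profile (Womersley number ~0.15,
# so the profile is quasi-steady).  Mid-gap speed follows from the section's
# speed-per-flux factor.  The reduction is validated against the transient
# ALE solver in the test suite.

#' Build a short-domain PVS flow model
#'
#' Precomputes the section quantities needed by the quasi-1D model: the
#' hydraulic resistance per unit length, the mid-gap speed per unit flow
#' rate, and the area sensitivity `S = dA/d(a*an)` to wall displacement
#' (inner wall moving with coefficient -1 against the outward normal, outer
#' wall with `+phi_sas`, fillets blended by the quintic smooth step).
#'
#' @param geometry `"lobed"` (the realistic two-lobed section) or
#'   `"annulus"` (concentric annulus of the same radii).
#' @param R1 arterial radius, m.
#' @param R2 outer radius / ellipse major semi-axis, m.
#' @param phi_sas outer-wall displacement scale (0 rigid, 0.368 compliant).
#' @param L segment length, m.
#' @param c pulse wave speed, m/s.
#' @param mu,rho fluid viscosity and density.
#' @param target_edge_length mesh resolution for the lobed section.
#' @return a `short_domain_model` with the section constants.
#' @export
short_domain_model <- function(geometry = c("lobed", "annulus"),
                               R1 = 30e-6, R2 = 70e-6, phi_sas = 0.368,
                               L = 5e-3, c = 1, mu = 1e-3, rho = 1000,
                               target_edge_length = 2e-6) {
  geometry <- match.arg(geometry)
  if (geometry == "lobed") {
    built <- build_lobed_section(R1, a_out = R2,
                                 target_edge_length = target_edge_length)
    base <- lobed_poiseuille(built, mu, dpdz = -1)  # unit favourable gradient
    Rf <- 1 / base$Q                                # resistance per length
    kf <- base$v_mid / base$Q                       # mid-gap speed per flux
    A0 <- base$area
    # area sensitivity: closed boundary integral of the displacement
    # coefficient (both lobes)
    S <- 2 * .lobe_area_sensitivity(built, phi_sas)
    per <- base$perimeter
  } else {
    built <- NULL
    Rf <- annular_resistance(R1, R2, mu)
    A0 <- pi * (R2^2 - R1^2)
    r0 <- (R1 + R2) / 2
    kf <- .annulus_midgap_per_flux(R1, R2, r0, mu)
    S <- 2 * pi * (phi_sas * R2 - R1)
    per <- 2 * pi * (R1 + R2)
  }
  structure(list(geometry = geometry, R1 = R1, R2 = R2, phi_sas = phi_sas,
                 L = L, c = c, mu = mu, rho = rho,
                 R_flow = Rf, k_mid = kf, A0 = A0, S = S,
                 perimeter = per, built = built),
            class = "short_domain_model")
}

# mid-gap speed per unit flux for the annular profile
.annulus_midgap_per_flux <- function(r1, r2, r0, mu) {
  g <- -1
  a <- g / (4 * mu)
  M <- rbind(c(log(r1), 1), c(log(r2), 1))
  C <- solve(M, c(-a * r1^2, -a * r2^2))
  w0 <- a * r0^2 + C[1] * log(r0) + C[2]
  Q <- -g / annular_resistance(r1, r2, mu)
  w0 / Q
}

# closed-boundary integral of the displacement coefficient over one lobe:
# dA/d(a*an) for that lobe
.lobe_area_sensitivity <- function(built, phi_sas) {
  mesh <- built$mesh
  tot <- 0
  for (side in c("inner", "outer", "endA", "endB")) {
    fq <- .mesh_face_quad(mesh, side)
    region <- switch(side, inner = "inner_wall", outer = "outer_wall",
                     "transition")
    for (q in 1:3) {
      g <- fq$quad[[q]]
      if (region == "transition") {
        # arc fraction of the quadrature points on the fillet
        sec <- built$section
        upper <- side == "endB"
        cen <- sec$fillet_center * c(1, if (upper) 1 else -1)
        tc <- sec$tangent_circle * c(1, if (upper) 1 else -1)
        te <- sec$tangent_ellipse * c(1, if (upper) 1 else -1)
        a1 <- atan2(tc[2] - cen[2], tc[1] - cen[1])
        a2 <- atan2(te[2] - cen[2], te[1] - cen[1])
        da <- ((a2 - a1 + pi) %% (2 * pi)) - pi
        ap <- atan2(g$y - cen[2], g$x - cen[1])
        sfr <- (((ap - a1 + pi) %% (2 * pi)) - pi) / da
        coef <- -1 + (1 + phi_sas) * smoothstep_quintic(sfr)
      } else {
        coef <- if (region == "inner_wall") -1 else phi_sas
      }
      tot <- tot + sum(g$w * coef)
    }
  }
  tot
}

#' Run the quasi-1D short-domain simulation
#'
#' Wall motion `a * an(t - z/c)` (inner wall outward = arterial dilation;
#' outer wall scaled by `phi_sas`) plus an applied pressure difference `p1`
#' between the proximal (z = 0) and distal (z = L, open) ends.  Mass
#' conservation gives the axial flux
#' `Q(z, t) = Q0(t) - S a int_0^z an'(t - z'/c) dz'` and the end pressures
#' fix `Q0(t)` through the (geometry-frozen) resistance.  Mid-gap speed is
#' `k_mid * Q`.
#'
#' @param model a [short_domain_model()].
#' @param waveform a `pulse_waveform`.
#' @param a wall displacement amplitude, m.
#' @param p1 applied pressure difference across the segment, Pa.
#' @param probe_z probe position, m (default 4 mm: 1 mm from the distal
#'   end).
#' @param times sample times, s (default 2 cycles at 400 samples/cycle).
#' @param nzgrid axial quadrature points.
#' @return list with the probe series data.frame (`t`, `v` mid-gap axial
#'   velocity, `wall_vr` inner-wall radial velocity), the mean/oscillatory
#'   decomposition, phase (degrees), and the trajectory of a particle
#'   released at the probe.
#' @export
run_short_domain <- function(model, waveform, a, p1 = 0,
                             probe_z = 4e-3,
                             times = NULL, nzgrid = 101L) {
  stopifnot(inherits(model, "short_domain_model"),
            inherits(waveform, "pulse_waveform"))
  f <- waveform$f
  if (is.null(times)) times <- seq(0, 2 / f, length.out = 801L)
  L <- model$L
  zg <- seq(0, L, length.out = nzgrid)
  dz <- zg[2] - zg[1]
  Qfun <- function(t, z) {
    # squeeze part: - S a int_0^z an'(t - z'/c) dz'
    dand <- model$S * a * waveform$dan(t - zg / model$c)
    cums <- c(0, cumsum((dand[-1] + dand[-nzgrid]) / 2 * dz))
    # Q0 from p(0) - p(L) = p1 = R int_0^L Q dz
    intc <- sum((cums[-1] + cums[-nzgrid]) / 2 * dz)
    Q0 <- p1 / (model$R_flow * L) + intc / L
    Q0 - stats::approx(zg, cums, xout = z)$y
  }
  v <- vapply(times, function(t) model$k_mid * Qfun(t, probe_z), 0)
  wall_vr <- a * waveform$dan(times - probe_z / model$c)
  pr <- data.frame(t = times, v = v, wall_vr = wall_vr)
  dec <- decompose_flow(v, f, t = times)
  phase <- tryCatch(phase_difference(wall_vr, v, f, times),
                    error = function(e) NA_real_)
  # particle released at the probe: z-pathline in the quasi-1D field
  field <- function(x, z, t) list(ur = 0, uz = model$k_mid * Qfun(t, z))
  traj <- advect_particle(field, x0 = c(0, probe_z), t0 = 0,
                          duration = 2 / f, dt = 1 / (1000 * f))
  dec_traj <- decompose_flow(traj, f)
  list(probe = pr, decomposition = dec, phase_deg = phase,
       trajectory = traj, decomposition_particle = dec_traj,
       a = a, p1 = p1, probe_z = probe_z)
}

#' Tune the wall-motion amplitude to an oscillatory-velocity target
#'
#' The quasi-1D model is linear in the amplitude `a`, so the amplitude that
#' produces a requested peak-to-peak mid-gap oscillatory velocity at the
#' probe follows from one trial run by exact scaling.
#'
#' @param model a [short_domain_model()].
#' @param waveform a `pulse_waveform`.
#' @param target_osc target peak-to-peak oscillatory velocity, m/s (the
#'   in-vivo range is 10-20 um/s; default 15 um/s).
#' @param probe_z probe position, m.
#' @return amplitude `a` in m.
#' @export
tune_short_domain_amplitude <- function(model, waveform,
                                        target_osc = 15e-6,
                                        probe_z = 4e-3) {
  trial <- 0.1e-6
  r <- run_short_domain(model, waveform, a = trial, p1 = 0, probe_z = probe_z)
  osc <- r$decomposition$oscillatory_velocity
  if (osc <= 0) stop("trial run produced no oscillation; waveform degenerate?")
  trial * target_osc / osc
}
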