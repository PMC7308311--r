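# Prescribed wall motions: the traveling sinusoidal peristaltic wave of the
# idealised annular model, the synthetic cardiac pulse waveform standing in
# for the in-vivo arterial pulsation (reported only graphically in the
# source measurements), and the region-resolved normal-direction wall
# displacement of the realistic lobed cross-section.

#' Peristaltic traveling-wave specification
#'
#' @param phi0 half-wave amplitude as a fraction of the inner radius R1,
#'   dimensionless (`0 <= phi0 < 1`).
#' @param c wave speed, m/s.
#' @param f frequency, Hz.
#' @return a `peristaltic_wave` with wavelength `lambda = c / f` (so
#'   `lambda * f == c` exactly).
#' @export
wave_spec <- function(phi0, c = 1, f = 8.67) {
  if (!is.finite(phi0) || phi0 < 0 || phi0 >= 1)
    stop("phi0 must satisfy 0 <= phi0 < 1 (got ", phi0, ")")
  if (c <= 0) stop("c must be positive (got ", c, ")")
  if (f <= 0) stop("f must be positive (got ", f, ")")
  structure(list(phi0 = phi0, c = c, f = f, lambda = c / f),
            class = "peristaltic_wave")
}

#' Amplitude conventions
#'
#' The pulsation amplitude appears in three equivalent forms.  With
#' half-wave amplitude `phi0` (fraction of R1, the quantity in the traveling
#' wave), the peak-to-peak radius excursion is `2 * phi0 * R1`, so
#'
#' * peak-to-peak change as % of the radius: `200 * phi0`;
#' * peak-to-peak change as % of the diameter (equivalently, the half-wave
#'   amplitude as % of the radius): `100 * phi0`.
#'
#' Physiological heart-beat pulsations correspond to 1-4% peak-to-peak of
#' radius, i.e. `phi0` of 0.005-0.02.
#'
#' @param pct percentage.
#' @return `phi0` (dimensionless half-wave fraction of R1).
#' @export
amp_from_pp_radius_pct <- function(pct) pct / 200

#' @rdname amp_from_pp_radius_pct
#' @export
amp_from_halfwave_pct <- function(pct) pct / 100

#' @rdname amp_from_pp_radius_pct
#' @param phi0 half-wave amplitude fraction.
#' @export
pp_radius_pct_from_amp <- function(phi0) 200 * phi0

#' Sinusoidal traveling-wave wall displacement
#'
#' Radial displacement of the inner (arterial) wall,
#' `u_mr = phi0 * R1 * sin(2*pi*(z - c*t)/lambda)`; the axial component is
#' zero.
#'
#' @param spec a [wave_spec()].
#' @param R1 baseline inner radius, m.
#' @param z axial position(s), m.
#' @param t time, s.
#' @return list with components `ur` and `uz` (vectors matching `z`).
#' @export
sinusoidal_displacement <- function(spec, R1, z, t) {
  stopifnot(inherits(spec, "peristaltic_wave"))
  ur <- spec$phi0 * R1 * sin(2 * pi * (z - spec$c * t) / spec$lambda)
  list(ur = ur, uz = rep(0, length(ur)))
}

#' @rdname sinusoidal_displacement
#' @details `sinusoidal_wall_velocity()` is the exact analytic time
#'   derivative of the displacement.
#' @export
sinusoidal_wall_velocity <- function(spec, R1, z, t) {
  stopifnot(inherits(spec, "peristaltic_wave"))
  k <- 2 * pi / spec$lambda
  vr <- -spec$phi0 * R1 * k * spec$c * cos(k * (z - spec$c * t))
  list(vr = vr, vz = rep(0, length(vr)))
}

# Pulse waveform -------------------------------------------------------------

#' Synthetic cardiac pulse waveform
#'
#' A smooth periodic shape function `an(t)` with period `1/f`, a single
#' systolic peak per cycle (fast upstroke over `upstroke_frac` of the cycle,
#' slower decay over the rest), normalised so `max(|an|) = 1` and zero time
#' average.  Built as a truncated Fourier series (default 3 harmonics) fitted
#' to a piecewise-cosine reference pulse, so the result is analytic with an
#' exact derivative.  `shape = "cosine"` gives the pure sinusoid
#' `an(t) = cos(2*pi*f*t)`.
#'
#' @param f frequency, Hz.
#' @param upstroke_frac fraction of the cycle occupied by the systolic
#'   upstroke (default 0.25).
#' @param n_harmonics number of Fourier harmonics retained.
#' @param shape `"cardiac"` (default) or `"cosine"`.
#' @return a `pulse_waveform`: list with the shape function `an(t)`, its
#'   analytic derivative `dan(t)` (1/s), frequency `f`, and the Fourier
#'   coefficients.
#' @export
synth_pulse_waveform <- function(f, upstroke_frac = 0.25, n_harmonics = 3L,
                                 shape = c("cardiac", "cosine")) {
  shape <- match.arg(shape)
  if (f <= 0) stop("f must be positive (got ", f, ")")
  if (shape == "cardiac" &&
      (upstroke_frac <= 0 || upstroke_frac >= 1))
    stop("upstroke_frac must lie in (0, 1) (got ", upstroke_frac, ")")
  if (shape == "cosine") {
    coef <- list(a = c(1), b = c(0))
  } else {
    # reference pulse on one cycle: -cos rise over [0, uf], cos decay after
    uf <- upstroke_frac
    ref <- function(s) ifelse(s < uf,
                              0.5 - 0.5 * cos(pi * s / uf),
                              0.5 + 0.5 * cos(pi * (s - uf) / (1 - uf)))
    n <- 2048L
    s <- (seq_len(n) - 0.5) / n
    y <- ref(s)
    a <- vapply(seq_len(n_harmonics),
                function(k) 2 * mean(y * cos(2 * pi * k * s)), 0)
    b <- vapply(seq_len(n_harmonics),
                function(k) 2 * mean(y * sin(2 * pi * k * s)), 0)
    coef <- list(a = a, b = b)
  }
  mk <- function(a, b, f) {
    force(a); force(b); force(f)
    an_raw <- function(t) {
      out <- 0
      for (k in seq_along(a))
        out <- out + a[k] * cos(2 * pi * k * f * t) + b[k] * sin(2 * pi * k * f * t)
      out
    }
    dan_raw <- function(t) {
      out <- 0
      for (k in seq_along(a)) {
        w <- 2 * pi * k * f
        out <- out + w * (-a[k] * sin(w * t) + b[k] * cos(w * t))
      }
      out
    }
    list(an = an_raw, dan = dan_raw)
  }
  raw <- mk(coef$a, coef$b, f)
  tt <- seq(0, 1 / f, length.out = 4096L)
  peak <- max(abs(raw$an(tt)))
  coef$a <- coef$a / peak; coef$b <- coef$b / peak
  fns <- mk(coef$a, coef$b, f)
  structure(list(an = fns$an, dan = fns$dan, f = f, period = 1 / f,
                 coef = coef, shape = shape, upstroke_frac = upstroke_frac),
            class = "pulse_waveform")
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf("<pulse_waveform> %s, f = %.3f Hz (period %.5f s), %d harmonics\n",
              x$shape, x$f, x$period, length(x$coef$a)))
  invisible(x)
}

#' Fit a pulse waveform to sampled data
#'
#' Builds a `pulse_waveform` from a sampled periodic series (e.g. a digitised
#' measured pulsation) by least-squares Fourier fitting, then normalises to
#' `max(|an|) = 1` and zero mean.
#'
#' @param time,an sampled series covering at least one period.
#' @param f frequency, Hz.
#' @param n_harmonics harmonics retained.
#' @return a `pulse_waveform`.
#' @export
fit_pulse_waveform <- function(time, an, f, n_harmonics = 8L) {
  stopifnot(length(time) == length(an), length(time) > 2 * n_harmonics + 1)
  X <- do.call(cbind, c(
    lapply(seq_len(n_harmonics), function(k) cos(2 * pi * k * f * time)),
    lapply(seq_len(n_harmonics), function(k) sin(2 * pi * k * f * time))))
  cf <- stats::lm.fit(X, an - mean(an))$coefficients
  cf[is.na(cf)] <- 0
  wf <- synth_pulse_waveform(f, shape = "cosine")
  wf$coef <- list(a = unname(cf[seq_len(n_harmonics)]),
                  b = unname(cf[n_harmonics + seq_len(n_harmonics)]))
  # renormalise and rebuild closures
  rebuild <- synth_pulse_waveform(f, shape = "cosine")
  tt <- seq(0, 1 / f, length.out = 4096L)
  mkan <- function(a, b) function(t) {
    out <- 0
    for (k in seq_along(a))
      out <- out + a[k] * cos(2 * pi * k * f * t) + b[k] * sin(2 * pi * k * f * t)
    out
  }
  mkdan <- function(a, b) function(t) {
    out <- 0
    for (k in seq_along(a)) {
      w <- 2 * pi * k * f
      out <- out + w * (-a[k] * sin(w * t) + b[k] * cos(w * t))
    }
    out
  }
  pk <- max(abs(mkan(wf$coef$a, wf$coef$b)(tt)))
  a <- wf$coef$a / pk; b <- wf$coef$b / pk
  structure(list(an = mkan(a, b), dan = mkdan(a, b), f = f, period = 1 / f,
                 coef = list(a = a, b = b), shape = "fitted",
                 upstroke_frac = NA_real_),
            class = "pulse_waveform")
}

#' Read/write a waveform as two-column CSV (time, an)
#'
#' @param waveform a `pulse_waveform`.
#' @param path file path.
#' @param n samples per period on export.
#' @export
write_waveform_csv <- function(waveform, path, n = 200L) {
  # n uniform samples over one period without a duplicated endpoint, so a
  # Fourier re-fit of the exported series is leakage-free
  t <- (seq_len(n) - 1L) / n * waveform$period
  utils::write.csv(data.frame(time = t, an = waveform$an(t)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param f frequency of the sampled waveform, Hz; if `NULL`, taken as the
#'   reciprocal of the sampled span.
#' @param n_harmonics harmonics retained in the fit.
#' @export
read_waveform_csv <- function(path, f = NULL, n_harmonics = 8L) {
  d <- utils::read.csv(path)
  if (is.null(f)) f <- 1 / (max(d[[1]]) - min(d[[1]]))
  fit_pulse_waveform(d[[1]], d[[2]], f, n_harmonics)
}

# Region-resolved 3D wall displacement ---------------------------------------

#' Quintic smooth step
#'
#' `S(x) = 6x^5 - 15x^4 + 10x^3` on `[0, 1]` (clamped outside): zero first
#' and second derivatives at both ends, so blended boundary data are C^2 at
#' the junctions.
#'
#' @param x evaluation points.
#' @export
smoothstep_quintic <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (10 + x * (-15 + 6 * x))
}

#' Boundary points of the lobed section with region labels and normals
#'
#' Extracts the wall nodes of a meshed lobe with their region label
#' (`inner_wall`: circular arc, `outer_wall`: elliptic arc, `transition`:
#' fillet arcs), outward unit normal (pointing out of the fluid) and, on the
#' fillets, the arc-length fraction `s_fillet` from the circle tangency (0)
#' to the ellipse tangency (1).
#'
#' @param built output of [build_lobed_section()].
#' @return data.frame with columns `x`, `y`, `region`, `nx`, `ny`,
#'   `s_fillet`, `node`.
#' @export
lobed_boundary_points <- function(built) {
  mesh <- built$mesh; sec <- built$section
  rows <- list()
  grab <- function(side, region) {
    ids <- mesh_boundary_nodes(mesh, side)
    data.frame(x = mesh$x[ids], y = mesh$y[ids], region = region,
               node = ids, stringsAsFactors = FALSE)
  }
  inner <- grab("inner", "inner_wall")
  outer <- grab("outer", "outer_wall")
  fb <- grab("endA", "transition")
  ft <- grab("endB", "transition")
  # normals: inner wall -> toward the artery center (out of the fluid)
  rin <- sqrt(inner$x^2 + inner$y^2)
  inner$nx <- -inner$x / rin; inner$ny <- -inner$y / rin
  # outer wall (ellipse): outward gradient of (x/a)^2 + (y/b)^2
  gx <- outer$x / sec$a_out^2; gy <- outer$y / sec$b_out^2
  gn <- sqrt(gx^2 + gy^2)
  outer$nx <- gx / gn; outer$ny <- gy / gn
  # fillets: normal points away from the fillet center (out of the fluid)
  fil <- function(d, upper) {
    cen <- sec$fillet_center * c(1, if (upper) 1 else -1)
    dx <- d$x - cen[1]; dy <- d$y - cen[2]
    dn <- sqrt(dx^2 + dy^2)
    d$nx <- dx / dn; d$ny <- dy / dn
    # arc fraction from circle-tangency to ellipse-tangency
    tc <- sec$tangent_circle * c(1, if (upper) 1 else -1)
    te <- sec$tangent_ellipse * c(1, if (upper) 1 else -1)
    a1 <- atan2(tc[2] - cen[2], tc[1] - cen[1])
    a2 <- atan2(te[2] - cen[2], te[1] - cen[1])
    da <- ((a2 - a1 + pi) %% (2 * pi)) - pi
    ap <- atan2(dy, dx)
    d$s_fillet <- (((ap - a1 + pi) %% (2 * pi)) - pi) / da
    d
  }
  inner$s_fillet <- NA_real_; outer$s_fillet <- NA_real_
  fb <- fil(fb, upper = FALSE); ft <- fil(ft, upper = TRUE)
  out <- rbind(inner, outer, fb, ft)
  out[!duplicated(out$node), ]
}

#' Region-resolved wall displacement of the lobed PVS
#'
#' Displacement of a labelled boundary point at axial position `z` and time
#' `t`, driven by the pulse waveform evaluated at the retarded time
#' `t - z/c`:
#' inner wall `u = -a * an(t - z/c) * n` (arterial dilation pushes the wall
#' against the outward fluid normal, narrowing the PVS); outer wall
#' `u = +phi_sas * a * an(t - z/c) * n`; on the fillet transition the
#' coefficient is blended from `-1` to `+phi_sas` by a quintic smooth step in
#' the arc-length fraction, so displacement is C^1 along the boundary.
#'
#' @param waveform a `pulse_waveform`.
#' @param points data.frame from [lobed_boundary_points()] (or any frame
#'   with `region`, `nx`, `ny`, `s_fillet`).
#' @param z axial position, m.
#' @param t time, s.
#' @param a displacement amplitude, m.
#' @param phi_sas outer-wall displacement scale (0 rigid outer wall, 0.368
#'   compliant).
#' @param c wave speed, m/s (retarded-time argument `t - z/c`).
#' @return list with displacement components `ux`, `uy` and velocity
#'   components `vx`, `vy` at each point.
#' @export
wall_displacement_3d <- function(waveform, points, z, t, a, phi_sas = 0.368,
                                 c = 1) {
  stopifnot(inherits(waveform, "pulse_waveform"))
  if (!all(points$region %in% c("inner_wall", "outer_wall", "transition")))
    stop("boundary point without a valid region label")
  coef <- ifelse(points$region == "inner_wall", -1,
          ifelse(points$region == "outer_wall", phi_sas,
                 -1 + (1 + phi_sas) * smoothstep_quintic(points$s_fillet)))
  if (any(points$region == "transition" & !is.finite(points$s_fillet)))
    stop("transition point lacks an arc-length fraction s_fillet")
  anv <- waveform$an(t - z / c)
  danv <- waveform$dan(t - z / c)
  list(ux = coef * a * anv * points$nx,
       uy = coef * a * anv * points$ny,
       vx = coef * a * danv * points$nx,
       vy = coef * a * danv * points$ny)
}
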