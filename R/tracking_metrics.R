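# Passive particle tracking and flow statistics: mean-vs-oscillatory
# decomposition of centerline series, wall-to-fluid phase difference, and
# mesh-convergence error norms.  Particles are tracked in physical (lab)
# coordinates using the physical-frame velocity; observable trajectories are
# frame-independent, so no ALE-specific bookkeeping is needed.

#' Advect a passive particle through a velocity field
#'
#' Classical RK4 pathline integration.  The velocity field is supplied as a
#' function `field(x, z, t)` returning `list(ur, uz)` (or `list(ux, uy)`)
#' in m/s — e.g. [wave_frame_field()] or an interpolant over transient
#' snapshots.
#'
#' @param field velocity field function.
#' @param x0 initial position `c(transverse, axial)`, m.
#' @param t0 release time, s.
#' @param duration tracking time, s.
#' @param dt time step, s (should resolve the cycle; default 1/1000 of
#'   `duration`).
#' @param record keep every `record`-th step in the output.
#' @param inside optional predicate `inside(x, z, t)`; integration stops
#'   with `exited = TRUE` when it returns `FALSE`.
#' @return a `trajectory`: data.frame with `t`, `x`, `z` plus attribute
#'   `exited`.
#' @export
advect_particle <- function(field, x0, t0 = 0, duration, dt = duration / 1000,
                            record = 1L, inside = NULL) {
  nstep <- ceiling(duration / dt)
  out <- matrix(NA_real_, nstep + 1L, 3L)
  colnames(out) <- c("t", "x", "z")
  pos <- x0; t <- t0
  out[1L, ] <- c(t, pos)
  exited <- FALSE
  vel <- function(p, tt) {
    v <- field(p[1], p[2], tt)
    if (!is.null(v$ur)) c(v$ur, v$uz) else c(v$ux, v$uy)
  }
  kept <- 1L
  for (i in seq_len(nstep)) {
    if (!is.null(inside) && !inside(pos[1], pos[2], t)) { exited <- TRUE; break }
    k1 <- vel(pos, t)
    k2 <- vel(pos + dt / 2 * k1, t + dt / 2)
    k3 <- vel(pos + dt / 2 * k2, t + dt / 2)
    k4 <- vel(pos + dt * k3, t + dt)
    pos <- pos + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (i %% record == 0L || i == nstep) {
      kept <- kept + 1L
      out[kept, ] <- c(t, pos)
    }
  }
  traj <- as.data.frame(out[seq_len(kept), , drop = FALSE])
  attr(traj, "exited") <- exited
  class(traj) <- c("trajectory", class(traj))
  traj
}

#' Decompose a flow series into mean and oscillatory components
#'
#' For a particle trajectory: mean flow speed = net axial displacement per
#' cycle x frequency; oscillatory velocity = peak-to-peak axial velocity
#' within a cycle (velocity differenced from positions).  For an Eulerian
#' probe series of axial velocity: mean = time average, oscillatory =
#' max - min over the cycle.
#'
#' @param x a `trajectory` (from [advect_particle()]) or a numeric velocity
#'   series.
#' @param f cycle frequency, Hz.
#' @param t times for a plain velocity series (required then).
#' @return list with `mean_flow_speed` (m/s), `oscillatory_velocity`
#'   (peak-to-peak, m/s) and `ratio` (`Inf` for purely steady flow).
#' @export
decompose_flow <- function(x, f, t = NULL) {
  if (inherits(x, "trajectory")) {
    tt <- x$t; z <- x$z
    span <- max(tt) - min(tt)
    if (span * f < 1 - 1e-9)
      stop("trajectory must cover at least one full cycle (has ",
           signif(span * f, 3), ")")
    ncyc <- floor(span * f + 1e-9)
    tend <- min(tt) + ncyc / f
    zend <- stats::approx(tt, z, xout = tend)$y
    mean_speed <- (zend - z[1]) / (ncyc / f)
    v <- diff(z) / diff(tt)
    # restrict to the whole cycles used for the mean
    vin <- v[tt[-1] <= tend + 1e-12]
    osc <- diff(range(vin))
  } else {
    if (is.null(t)) stop("t must be supplied for a velocity series")
    span <- max(t) - min(t)
    if (span * f < 1 - 1e-9)
      stop("series must cover at least one full cycle (has ",
           signif(span * f, 3), ")")
    mean_speed <- mean(x)
    osc <- diff(range(x))
  }
  list(mean_flow_speed = mean_speed,
       oscillatory_velocity = osc,
       ratio = if (osc > 0) abs(mean_speed) / osc else Inf)
}

#' Phase difference between wall and fluid velocity series
#'
#' Extracts the fundamental Fourier component of each cycle-periodic series
#' at frequency `f` and reports the phase lag of the fluid behind the wall,
#' in degrees in `[0, 360)`.  Writing each series as
#' `A cos(2*pi*f*t - theta)`, the returned value is
#' `(theta_fluid - theta_wall) mod 360`: positive means fluid events occur
#' later in the cycle than the corresponding wall events (a quarter-period
#' delay of the fluid gives 90 degrees).
#'
#' @param wall,fluid numeric series sampled at common times `t`.
#' @param f fundamental frequency, Hz.
#' @param t sample times, s (need not start at 0; a uniform shift of both
#'   series leaves the result unchanged).
#' @return phase difference in degrees, `[0, 360)`.
#' @export
phase_difference <- function(wall, fluid, f, t) {
  stopifnot(length(wall) == length(fluid), length(wall) == length(t))
  ph <- function(s) {
    s <- s - mean(s)
    cc <- sum(s * exp(-2i * pi * f * t))
    if (Mod(cc) < 1e-12 * length(s) * max(abs(s), 1e-300) || all(s == 0))
      stop("fundamental amplitude below noise floor; phase undefined")
    # s ~ A cos(w t - theta): projection gives (A/2) e^{-i theta}
    -Arg(cc)
  }
  ((ph(fluid) - ph(wall)) * 180 / pi) %% 360
}

#' Relative L2 error norms between two refinement levels
#'
#' Integrates the velocity- and pressure-difference fields over the whole
#' domain on the finer mesh's quadrature, normalised by the finer solution:
#' `L2Err_v = sqrt(int |v_m - v_2m|^2) / sqrt(int |v_2m|^2)` (Euclidean norm
#' of the vector difference) and likewise for the pressure magnitude.
#' Fields are compared at matched times / matched material points via the
#' shared logical coordinates of the structured meshes.
#'
#' @param sol_m,sol_2m `wave_frame_solution`s (or any objects carrying
#'   `mesh`, lab-frame `ur_lab`/`uz_lab` and `p`) at refinement m and 2m of
#'   the same physical configuration.
#' @return list with `L2Err_v` and `L2Err_p` (dimensionless fractions).
#' @export
l2_error_norms <- function(sol_m, sol_2m) {
  if (!isTRUE(all.equal(sol_m$spec$phi0, sol_2m$spec$phi0)) ||
      !isTRUE(all.equal(sol_m$R1, sol_2m$R1)) ||
      !isTRUE(all.equal(sol_m$c, sol_2m$c)))
    stop("solutions come from different physical configurations")
  fine <- sol_2m$mesh; coarse <- sol_m$mesh
  gq <- .mesh_quad_geom(fine)
  # logical coordinates of the fine quadrature points
  ei <- rep(seq_len(fine$nr), times = fine$nz)
  ej <- rep(seq_len(fine$nz), each = fine$nr)
  num_v <- den_v <- num_p <- den_p <- 0
  for (q in 1:9) {
    qi <- (q - 1) %% 3 + 1; qj <- (q - 1) %/% 3 + 1
    s <- (ei - 1 + (GAUSS3_X[qi] + 1) / 2) / fine$nr
    tl <- (ej - 1 + (GAUSS3_X[qj] + 1) / 2) / fine$nz
    w <- gq[[q]]$w
    urf <- fem_eval_logical(fine, sol_2m$ur_lab, s, tl)
    uzf <- fem_eval_logical(fine, sol_2m$uz_lab, s, tl)
    pf <- fem_eval_logical(fine, sol_2m$p, s, tl)
    urc <- fem_eval_logical(coarse, sol_m$ur_lab, s, tl)
    uzc <- fem_eval_logical(coarse, sol_m$uz_lab, s, tl)
    pc <- fem_eval_logical(coarse, sol_m$p, s, tl)
    num_v <- num_v + sum(w * ((urc - urf)^2 + (uzc - uzf)^2))
    den_v <- den_v + sum(w * (urf^2 + uzf^2))
    num_p <- num_p + sum(w * (pc - pf)^2)
    den_p <- den_p + sum(w * pf^2)
  }
  list(L2Err_v = sqrt(num_v / den_v), L2Err_p = sqrt(num_p / den_p))
}
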