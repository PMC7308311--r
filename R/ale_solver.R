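# Arbitrary Lagrangian-Eulerian solver: time-dependent incompressible
# Navier-Stokes on a deforming mesh.  The mesh follows the prescribed wall
# motion through a componentwise Laplace (harmonic-extension) problem solved
# on the reference domain; the convective velocity is measured relative to
# the mesh velocity; time integration is BDF (first step backward Euler,
# then BDF2) with the convective term treated explicitly by second-order
# extrapolation — at the Reynolds numbers of PVS flow (Re << 1) the
# convective term is a small regular perturbation and explicit treatment is
# stable at the cardiac time steps used.

#' Fluid properties
#'
#' @param mu_f dynamic viscosity, Pa s (CSF: 1e-3).
#' @param rho_f mass density, kg/m^3 (CSF: 1000).
#' @export
fluid_properties <- function(mu_f = 1e-3, rho_f = 1000) {
  if (mu_f <= 0) stop("mu_f must be positive (got ", mu_f, ")")
  if (rho_f <= 0) stop("rho_f must be positive (got ", rho_f, ")")
  structure(list(mu_f = mu_f, rho_f = rho_f), class = "fluid_properties")
}

# Anisotropic non-dimensionalisation -----------------------------------------

#' Anisotropic scaling specification
#'
#' The PVS domains are extremely anisotropic (axial length up to ~3000x the
#' gap width).  Coordinates are non-dimensionalised with different factors
#' in the transverse and axial directions:
#' `X_m = L0 * diag(1, 1, g3) * X_c`, with `L0 = R1` and `g3` chosen so the
#' non-dimensional axial length is 10 (for the one-wavelength annulus,
#' `g3 = lambda / (10 * L0)`, about 385 with Table-1-like parameters).
#'
#' @param L0 characteristic transverse length, m (the arterial radius).
#' @param g3 axial scaling factor; if `NULL`, computed from `domain_length`.
#' @param domain_length physical axial length, m.
#' @export
scaling_spec <- function(L0, g3 = NULL, domain_length = NULL) {
  if (L0 <= 0) stop("L0 must be positive (got ", L0, ")")
  if (is.null(g3)) {
    if (is.null(domain_length)) stop("give g3 or domain_length")
    g3 <- domain_length / (10 * L0)
  }
  if (g3 <= 0) stop("g3 must be positive (got ", g3, ")")
  structure(list(L0 = L0, g3 = g3), class = "scaling_spec")
}

#' Map physical coordinates to non-dimensional computational coordinates
#'
#' @param coords list/data.frame with transverse `x` and axial `y` physical
#'   coordinates (m), or a `quad_mesh`.
#' @param spec a [scaling_spec()].
#' @return object of the same shape with scaled coordinates
#'   (`x/L0`, `y/(L0*g3)`); [redimensionalize()] is its exact inverse.
#' @export
nondimensionalize <- function(coords, spec) {
  stopifnot(inherits(spec, "scaling_spec"))
  if (inherits(coords, "quad_mesh")) {
    return(mesh_set_coords(coords, coords$xg / spec$L0,
                           coords$yg / (spec$L0 * spec$g3)))
  }
  list(x = coords$x / spec$L0, y = coords$y / (spec$L0 * spec$g3))
}

#' @rdname nondimensionalize
#' @export
redimensionalize <- function(coords, spec) {
  stopifnot(inherits(spec, "scaling_spec"))
  if (inherits(coords, "quad_mesh")) {
    return(mesh_set_coords(coords, coords$xg * spec$L0,
                           coords$yg * (spec$L0 * spec$g3)))
  }
  list(x = coords$x * spec$L0, y = coords$y * (spec$L0 * spec$g3))
}

#' Gradient anisotropy diagnostic
#'
#' RMS ratio of transverse to axial derivatives of a nodal field, evaluated
#' in the mesh (physical) coordinates and in the non-dimensional
#' computational coordinates.  On the one-wavelength annulus the physical
#' ratio is of order 1000 (gradients overwhelmingly radial); after the
#' anisotropic scaling it is of order 1.
#'
#' @param mesh a `quad_mesh`.
#' @param nodal a Q2 nodal field.
#' @param spec a [scaling_spec()].
#' @return list with `ratio_mesh` and `ratio_computational`.
#' @export
gradient_anisotropy <- function(mesh, nodal, spec) {
  gq <- .mesh_quad_geom(mesh)
  vals <- matrix(nodal[mesh$conn2], mesh$ne, 9)
  sx2 <- sy2 <- 0
  for (q in 1:9) {
    g <- .q2_grads(gq, q)
    dx <- rowSums(vals * g$gx); dy <- rowSums(vals * g$gy)
    w <- gq[[q]]$w
    sx2 <- sx2 + sum(w * dx^2); sy2 <- sy2 + sum(w * dy^2)
  }
  rmesh <- sqrt(sx2 / sy2)
  # computational-coordinate derivatives: d/dxc = L0 d/dx, d/dyc = L0 g3 d/dy
  list(ratio_mesh = rmesh, ratio_computational = rmesh / spec$g3)
}

# Mesh motion ----------------------------------------------------------------

#' Solve the mesh-motion Laplace problem
#'
#' Harmonic extension of prescribed boundary displacement into the domain:
#' `laplacian(u_m) = 0` componentwise on the reference mesh (planar
#' computational-domain Laplacian), with the given wall values, zero axial
#' displacement at non-periodic end faces, and natural conditions otherwise.
#'
#' @param mesh the reference `quad_mesh`.
#' @param boundary list with per-side displacement values:
#'   `list(inner = list(ux = ..., uy = ...), outer = ...)`; values are
#'   scalars or per-node vectors.
#' @param cache optional cache from [mesh_motion_operator()].
#' @return list with nodal displacement fields `ux`, `uy`.
#' @export
solve_mesh_motion <- function(mesh, boundary, cache = NULL) {
  if (is.null(cache)) cache <- mesh_motion_operator(mesh)
  ux <- .mm_solve(cache$x, .mm_boundary_vals(mesh, boundary, "ux", cache$x$dofs))
  uy <- .mm_solve(cache$y, .mm_boundary_vals(mesh, boundary, "uy", cache$y$dofs))
  list(ux = ux, uy = uy)
}

#' Prefactorised mesh-motion operator
#'
#' @param mesh the reference mesh.
#' @return cache for [solve_mesh_motion()]; factorised once, reused every
#'   time step.
#' @export
mesh_motion_operator <- function(mesh) {
  sc <- assemble_scalar(mesh, weight = "planar")
  walls <- c("inner", "outer")
  wall_dofs <- unique(unlist(lapply(walls, mesh_boundary_nodes, mesh = mesh)))
  end_dofs <- if (!mesh$periodic)
    unique(unlist(lapply(c("endA", "endB"), mesh_boundary_nodes, mesh = mesh)))
  else integer(0)
  mk <- function(dofs) {
    n <- nrow(sc$K)
    keep <- Matrix::Diagonal(n, x = as.numeric(!(seq_len(n) %in% dofs)))
    Kmod <- keep %*% sc$K %*% keep +
      Matrix::Diagonal(n, x = as.numeric(seq_len(n) %in% dofs))
    list(K = sc$K, lu = Matrix::lu(Matrix::drop0(Kmod)), dofs = dofs)
  }
  # transverse component: Dirichlet on walls only; axial component: walls
  # plus zero at end faces (short-domain runs keep the ends planar)
  list(x = mk(wall_dofs), y = mk(sort(unique(c(wall_dofs, end_dofs)))))
}

.mm_boundary_vals <- function(mesh, boundary, comp, dofs) {
  vals <- numeric(mesh$n2)
  for (side in names(boundary)) {
    ids <- mesh_boundary_nodes(mesh, side)
    v <- boundary[[side]][[comp]]
    if (!is.null(v)) vals[ids] <- rep_len(v, length(ids))
  }
  vals[dofs]
}

.mm_solve <- function(op, vals) {
  n <- nrow(op$K)
  xlift <- numeric(n); xlift[op$dofs] <- vals
  f <- -as.numeric(op$K %*% xlift)
  f[op$dofs] <- vals
  as.numeric(Matrix::solve(op$lu, f))
}

# Explicit convection right-hand side: integral( rho ((b . grad) a) . v )
.convection_rhs <- function(mesh, rho, bx, by, ax, ay) {
  st <- .shape_tables
  gq <- .mesh_quad_geom(mesh)
  ne <- mesh$ne; n2 <- mesh$n2
  Bxc <- matrix(bx[mesh$conn2], ne, 9); Byc <- matrix(by[mesh$conn2], ne, 9)
  Axc <- matrix(ax[mesh$conn2], ne, 9); Ayc <- matrix(ay[mesh$conn2], ne, 9)
  fxel <- fyel <- matrix(0, ne, 9)
  for (q in 1:9) {
    g <- .q2_grads(gq, q)
    w <- gq[[q]]$w
    bq1 <- as.numeric(Bxc %*% st$N2[q, ]); bq2 <- as.numeric(Byc %*% st$N2[q, ])
    daxdx <- rowSums(Axc * g$gx); daxdy <- rowSums(Axc * g$gy)
    daydx <- rowSums(Ayc * g$gx); daydy <- rowSums(Ayc * g$gy)
    convx <- bq1 * daxdx + bq2 * daxdy
    convy <- bq1 * daydx + bq2 * daydy
    for (a in 1:9) {
      fxel[, a] <- fxel[, a] + rho * w * st$N2[q, a] * convx
      fyel[, a] <- fyel[, a] + rho * w * st$N2[q, a] * convy
    }
  }
  accx <- rowsum(as.numeric(fxel), as.integer(mesh$conn2))
  accy <- rowsum(as.numeric(fyel), as.integer(mesh$conn2))
  fx <- numeric(n2); fy <- numeric(n2)
  fx[as.integer(rownames(accx))] <- accx
  fy[as.integer(rownames(accy))] <- accy
  list(fx = fx, fy = fy)
}

#' Advance the ALE flow solution by one time step
#'
#' One BDF step of the incompressible Navier-Stokes equations on the
#' deforming domain.  `state` carries the previous nodal fields on the
#' reference node set; `motion` prescribes the wall displacement/velocity at
#' any time.  Used internally by [run_transient()].
#'
#' @param state list with `ux`, `uy`, `p`, `t`, and optionally `ux_prev`,
#'   `uy_prev` (enables BDF2).
#' @param dt time step, s.
#' @param mesh_ref the reference (undeformed) mesh.
#' @param props [fluid_properties()].
#' @param motion wall-motion description: function `motion(t)` returning
#'   `list(disp = list(inner=list(ux,uy), outer=...), vel = ...)` with
#'   per-node values on each wall, or `NULL` for static walls.
#' @param bc list: `end` one of `"periodic"`, `"traction"`; `p1` applied
#'   pressure at `endA` (Pa, traction `-p1 n`), `p2` at `endB` (default 0).
#' @param body uniform body force `c(fx, fy)` or function of time.
#' @param mm_cache cache from [mesh_motion_operator()].
#' @param include_convection logical; drop the convective term entirely when
#'   `FALSE` (Stokes limit).
#' @return updated `state` (fields on the mesh deformed to `t + dt`,
#'   including the deformed `mesh` and mesh velocity `wx`, `wy`).
#' @export
ale_step <- function(state, dt, mesh_ref, props, motion, bc,
                     body = c(0, 0), mm_cache = NULL,
                     include_convection = TRUE, static_cache = NULL) {
  tn <- state$t + dt
  n2 <- mesh_ref$n2; n1 <- mesh_ref$n1
  moving <- !is.null(motion)
  if (moving) {
    if (is.null(mm_cache)) mm_cache <- mesh_motion_operator(mesh_ref)
    mo <- motion(tn)
    dsp <- solve_mesh_motion(mesh_ref, mo$disp, mm_cache)
    wvl <- solve_mesh_motion(mesh_ref, mo$vel, mm_cache)
    # displace geometry nodes (periodic: duplicate the first DOF column)
    gidx <- .geom_dof_map(mesh_ref)
    mesh <- mesh_set_coords(mesh_ref,
                            mesh_ref$xg + dsp$ux[gidx],
                            mesh_ref$yg + dsp$uy[gidx])
    wx <- wvl$ux; wy <- wvl$uy
  } else {
    mesh <- mesh_ref
    wx <- numeric(n2); wy <- numeric(n2)
    mo <- NULL
  }
  ops <- if (!is.null(static_cache)) static_cache$ops
         else assemble_stokes(mesh, props$mu_f)
  bdf2 <- !is.null(state$ux_prev)
  c0 <- if (bdf2) 3 / (2 * dt) else 1 / dt
  hist <- if (bdf2) {
    list(x = (4 * state$ux - state$ux_prev) / (2 * dt),
         y = (4 * state$uy - state$uy_prev) / (2 * dt))
  } else {
    list(x = state$ux / dt, y = state$uy / dt)
  }
  bodyv <- if (is.function(body)) body(tn) else body
  gauge <- identical(bc$end, "periodic")
  f <- numeric(2 * n2 + n1 + (if (gauge) 1L else 0L))
  f[1:n2] <- props$rho_f * as.numeric(ops$Mv[1:n2, 1:n2] %*% hist$x) +
    bodyv[1] * ops$bload
  f[n2 + 1:n2] <- props$rho_f * as.numeric(ops$Mv[1:n2, 1:n2] %*% hist$y) +
    bodyv[2] * ops$bload
  if (!gauge) {
    p1 <- if (is.null(bc$p1)) 0 else if (is.function(bc$p1)) bc$p1(tn) else bc$p1
    p2 <- if (is.null(bc$p2)) 0 else if (is.function(bc$p2)) bc$p2(tn) else bc$p2
    tl <- .traction_load(mesh, "endA", p1)
    f[1:n2] <- f[1:n2] + tl$fx; f[n2 + 1:n2] <- f[n2 + 1:n2] + tl$fy
    tl <- .traction_load(mesh, "endB", p2)
    f[1:n2] <- f[1:n2] + tl$fx; f[n2 + 1:n2] <- f[n2 + 1:n2] + tl$fy
  }
  if (include_convection) {
    # second-order extrapolated convected/convecting field, relative to mesh
    axs <- if (bdf2) 2 * state$ux - state$ux_prev else state$ux
    ays <- if (bdf2) 2 * state$uy - state$uy_prev else state$uy
    cv <- .convection_rhs(mesh, props$rho_f, axs - wx, ays - wy, axs, ays)
    f[1:n2] <- f[1:n2] - cv$fx
    f[n2 + 1:n2] <- f[n2 + 1:n2] - cv$fy
  }
  # wall Dirichlet: fluid velocity = wall velocity
  wall_vals <- if (moving) {
    list(inner = mo$vel$inner, outer = mo$vel$outer)
  } else {
    list(inner = list(ux = 0, uy = 0), outer = list(ux = 0, uy = 0))
  }
  bcv <- .vel_dirichlet(mesh, c("inner", "outer"),
                        lapply(wall_vals, `[[`, "ux"),
                        lapply(wall_vals, `[[`, "uy"))
  if (!is.null(static_cache)) {
    # static walls: matrix prefactorised, Dirichlet values are zero
    lu <- if (bdf2) static_cache$lu2 else static_cache$lu1
    f[bcv$dofs] <- 0
    sol <- as.numeric(Matrix::solve(lu, f))
  } else {
    Zpp <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n1, n1))
    K <- rbind(cbind(c0 * props$rho_f * ops$Mv + ops$A, -Matrix::t(ops$B)),
               cbind(-ops$B, Zpp))
    if (gauge) {
      gcol <- c(numeric(2 * n2), ops$gp)
      K <- rbind(cbind(K, gcol), c(gcol, 0))
    }
    sys <- apply_dirichlet(K, f, bcv$dofs, bcv$vals)
    sol <- as.numeric(Matrix::solve(sys$K, sys$f))
  }
  list(ux = sol[1:n2], uy = sol[n2 + 1:n2], p = sol[2 * n2 + 1:n1],
       t = tn, ux_prev = state$ux, uy_prev = state$uy,
       mesh = mesh, wx = wx, wy = wy)
}

# Prefactorised step matrices for static-wall runs (the mesh, and hence the
# system matrix, does not change between steps).
.static_step_cache <- function(mesh, props, bc, dt) {
  ops <- assemble_stokes(mesh, props$mu_f)
  n2 <- mesh$n2; n1 <- mesh$n1
  gauge <- identical(bc$end, "periodic")
  bcv <- .vel_dirichlet(mesh, c("inner", "outer"),
                        list(0, 0), list(0, 0))
  Zpp <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n1, n1))
  mk <- function(c0) {
    K <- rbind(cbind(c0 * props$rho_f * ops$Mv + ops$A, -Matrix::t(ops$B)),
               cbind(-ops$B, Zpp))
    if (gauge) {
      gcol <- c(numeric(2 * n2), ops$gp)
      K <- rbind(cbind(K, gcol), c(gcol, 0))
    }
    n <- nrow(K)
    keep <- Matrix::Diagonal(n, x = as.numeric(!(seq_len(n) %in% bcv$dofs)))
    Kmod <- keep %*% K %*% keep +
      Matrix::Diagonal(n, x = as.numeric(seq_len(n) %in% bcv$dofs))
    Matrix::lu(Matrix::drop0(Kmod))
  }
  list(ops = ops, lu1 = mk(1 / dt), lu2 = mk(3 / (2 * dt)))
}

# map geometry-node index -> DOF-node index (identity unless periodic, where
# the duplicated last axial column maps back to the first)
.geom_dof_map <- function(mesh) {
  if (!mesh$periodic) return(seq_len(mesh$n2))
  idx <- integer(mesh$Ni * mesh$Njg)
  for (j in seq_len(mesh$Njg)) {
    jd <- if (j == mesh$Njg) 1L else j
    idx[(j - 1L) * mesh$Ni + seq_len(mesh$Ni)] <-
      (jd - 1L) * mesh$Ni + seq_len(mesh$Ni)
  }
  idx
}

#' Run a transient ALE simulation
#'
#' Integrates from the given initial condition (rest by default) with fixed
#' time step `dt = 1/(f * steps_per_cycle)`, recording probe traces every
#' step and full states at `record_phases` phases of each cycle.  Flags the
#' first cycle at which cycle-periodicity is reached (relative nodal L2
#' change of the velocity field between consecutive cycles below `ptol`).
#'
#' @param mesh_ref reference `quad_mesh`.
#' @param props [fluid_properties()].
#' @param motion wall motion function (see [ale_step()]) or `NULL`.
#' @param bc boundary-condition list (see [ale_step()]).
#' @param f cycle frequency, Hz.
#' @param n_cycles number of cycles to integrate.
#' @param steps_per_cycle steps per cycle (default 1000, i.e. the maximum
#'   time step is 1/1000 of the cycle).
#' @param body uniform body force or function of time.
#' @param probes data.frame/list with `x`, `z` probe coordinates.
#' @param init optional initial state `list(ux, uy)`.
#' @param include_convection logical, see [ale_step()].
#' @param record_phases number of uniformly spaced phases per cycle at which
#'   full states are kept (default 100).
#' @param ptol cycle-periodicity tolerance (default 1e-4).
#' @return list with `states` (recorded snapshots), `probe` (per-step probe
#'   trace data.frame), `periodic_cycle` (first periodic cycle or `NA`),
#'   `cycle_change` (per-cycle relative change).
#' @export
run_transient <- function(mesh_ref, props, motion, bc, f,
                          n_cycles = 3, steps_per_cycle = 1000L,
                          body = c(0, 0), probes = NULL, init = NULL,
                          include_convection = TRUE,
                          record_phases = 100L, ptol = 1e-4) {
  dt <- 1 / (f * steps_per_cycle)
  mm_cache <- if (!is.null(motion)) mesh_motion_operator(mesh_ref)
  static_cache <- if (is.null(motion))
    .static_step_cache(mesh_ref, props, bc, dt)
  n2 <- mesh_ref$n2
  state <- list(ux = numeric(n2), uy = numeric(n2),
                p = numeric(mesh_ref$n1), t = 0)
  if (!is.null(init)) { state$ux <- init$ux; state$uy <- init$uy }
  nstep_total <- round(n_cycles * steps_per_cycle)
  rec_every <- max(1L, round(steps_per_cycle / record_phases))
  states <- list()
  probe_rows <- vector("list", nstep_total)
  cyc_end_u <- NULL; cycle_change <- numeric(0); periodic_cycle <- NA_integer_
  for (i in seq_len(nstep_total)) {
    state <- ale_step(state, dt, mesh_ref, props, motion, bc, body = body,
                      mm_cache = mm_cache, static_cache = static_cache,
                      include_convection = include_convection)
    if (!is.null(probes)) {
      msh <- state$mesh
      uzp <- fem_eval_points(msh, state$uy, probes$x, probes$z)
      urp <- fem_eval_points(msh, state$ux, probes$x, probes$z)
      probe_rows[[i]] <- data.frame(t = state$t,
                                    probe = seq_along(probes$x),
                                    ur = urp, uz = uzp)
    }
    if (i %% rec_every == 0L || i == nstep_total) {
      states[[length(states) + 1L]] <-
        list(t = state$t, ux = state$ux, uy = state$uy, p = state$p,
             mesh = state$mesh)
    }
    if (i %% steps_per_cycle == 0L) {
      u <- c(state$ux, state$uy)
      if (!is.null(cyc_end_u)) {
        ch <- sqrt(sum((u - cyc_end_u)^2)) / max(sqrt(sum(u^2)), 1e-300)
        cycle_change <- c(cycle_change, ch)
        if (is.na(periodic_cycle) && ch < ptol)
          periodic_cycle <- i %/% steps_per_cycle
      } else if (sqrt(sum(u^2)) == 0) {
        # identically zero flow is periodic from the first cycle
        cycle_change <- c(cycle_change, 0)
        periodic_cycle <- 1L
      }
      cyc_end_u <- u
    }
  }
  if (is.na(periodic_cycle) && length(cycle_change) &&
      utils::tail(cycle_change, 1) < ptol)
    periodic_cycle <- n_cycles
  if (is.na(periodic_cycle) && length(cycle_change))
    warning(sprintf(
      "cycle-periodicity not reached in %d cycles (last relative change %.2e)",
      n_cycles, utils::tail(cycle_change, 1)))
  list(states = states,
       probe = if (!is.null(probes)) do.call(rbind, probe_rows),
       periodic_cycle = periodic_cycle, cycle_change = cycle_change,
       dt = dt, state = state)
}
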