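# Mixed Q2/Q1 (Taylor-Hood type) assembly of the incompressible flow
# equations on a quad_mesh, in the Cauchy-stress (symmetric gradient) form:
#   momentum:   rho (du/dt + (a . grad) u) = div sigma + f,
#   sigma = -p I + mu (grad u + grad u^T),   div u = 0.
# Planar meshes use the 2D Cartesian operators; axisymmetric meshes carry the
# 2*pi*r measure, the hoop strain term 2*mu*(u_r v_r)/r^2 and the u_r/r
# divergence contribution (no swirl).

#' Assemble flow operators on a mesh
#'
#' Returns the viscous (stress-form) matrix `A` on velocity, the divergence
#' matrix `B` (pressure test x velocity trial), the unit-density velocity
#' mass matrix `Mv`, the pressure integral vector `gp` and the velocity load
#' vectors `bx`, `by` for unit body force per component.
#'
#' @param mesh a `quad_mesh`.
#' @param mu dynamic viscosity, Pa s.
#' @return list of sparse operators; velocity DOFs are ordered x-component
#'   first (`1..n2`), then y-component (`n2+1..2*n2`).
#' @keywords internal
assemble_stokes <- function(mesh, mu) {
  st <- .shape_tables
  gq <- .mesh_quad_geom(mesh)
  ne <- mesh$ne; n2 <- mesh$n2; n1 <- mesh$n1
  Axx <- Axy <- Ayx <- Ayy <- Mel <- matrix(0, ne, 81)
  Bx <- By <- matrix(0, ne, 36)
  gpel <- matrix(0, ne, 4)
  bel <- matrix(0, ne, 9)
  for (q in 1:9) {
    g <- .q2_grads(gq, q)
    w <- gq[[q]]$w
    N <- st$N2[q, ]
    if (mesh$axisym) {
      rinv <- 1 / gq[[q]]$x
    }
    for (b in 1:9) {
      gxb <- g$gx[, b]; gyb <- g$gy[, b]
      for (a in 1:9) {
        idx <- (b - 1) * 9 + a
        gxa <- g$gx[, a]; gya <- g$gy[, a]
        Axx[, idx] <- Axx[, idx] + mu * w * (2 * gxa * gxb + gya * gyb)
        Axy[, idx] <- Axy[, idx] + mu * w * (gya * gxb)
        Ayx[, idx] <- Ayx[, idx] + mu * w * (gxa * gyb)
        Ayy[, idx] <- Ayy[, idx] + mu * w * (2 * gya * gyb + gxa * gxb)
        Mel[, idx] <- Mel[, idx] + w * N[a] * N[b]
        if (mesh$axisym)
          Axx[, idx] <- Axx[, idx] + mu * w * 2 * N[a] * N[b] * rinv^2
      }
      bel[, b] <- bel[, b] + w * N[b]
    }
    for (p_ in 1:4) {
      Np <- st$N1[q, p_]
      gpel[, p_] <- gpel[, p_] + w * Np
      for (b in 1:9) {
        idx <- (b - 1) * 4 + p_
        div_b_x <- g$gx[, b] + if (mesh$axisym) st$N2[q, b] * rinv else 0
        Bx[, idx] <- Bx[, idx] + w * Np * div_b_x
        By[, idx] <- By[, idx] + w * Np * g$gy[, b]
      }
    }
  }
  Axx <- .block_sparse(Axx, mesh$conn2, mesh$conn2, 9, 9, n2, n2)
  Axy <- .block_sparse(Axy, mesh$conn2, mesh$conn2, 9, 9, n2, n2)
  Ayx <- .block_sparse(Ayx, mesh$conn2, mesh$conn2, 9, 9, n2, n2)
  Ayy <- .block_sparse(Ayy, mesh$conn2, mesh$conn2, 9, 9, n2, n2)
  A <- rbind(cbind(Axx, Axy), cbind(Ayx, Ayy))
  Bxs <- .block_sparse(Bx, mesh$conn1, mesh$conn2, 4, 9, n1, n2)
  Bys <- .block_sparse(By, mesh$conn1, mesh$conn2, 4, 9, n1, n2)
  B <- cbind(Bxs, Bys)
  M1 <- .block_sparse(Mel, mesh$conn2, mesh$conn2, 9, 9, n2, n2)
  Mv <- Matrix::bdiag(M1, M1)
  acc <- rowsum(as.numeric(gpel), as.integer(mesh$conn1))
  gp <- numeric(n1); gp[as.integer(rownames(acc))] <- acc
  accb <- rowsum(as.numeric(bel), as.integer(mesh$conn2))
  bv <- numeric(n2); bv[as.integer(rownames(accb))] <- accb
  list(A = A, B = B, Mv = Mv, gp = gp, bload = bv)
}

#' Assemble the Oseen convection matrix for a given convecting field
#'
#' `C[v,u] = integral( rho ((a . grad) u) . v )` with the nodal convecting
#' velocity `a = (ax, ay)`; the same scalar block acts on both velocity
#' components (no swirl).
#'
#' @keywords internal
assemble_convection <- function(mesh, rho, ax, ay) {
  st <- .shape_tables
  gq <- .mesh_quad_geom(mesh)
  ne <- mesh$ne; n2 <- mesh$n2
  Axc <- matrix(ax[mesh$conn2], ne, 9)
  Ayc <- matrix(ay[mesh$conn2], ne, 9)
  Cel <- matrix(0, ne, 81)
  for (q in 1:9) {
    g <- .q2_grads(gq, q)
    w <- gq[[q]]$w
    aq <- Axc %*% st$N2[q, ]; bq <- Ayc %*% st$N2[q, ]
    for (b in 1:9) {
      adv <- as.numeric(aq) * g$gx[, b] + as.numeric(bq) * g$gy[, b]
      for (a in 1:9) {
        idx <- (b - 1) * 9 + a
        Cel[, idx] <- Cel[, idx] + rho * w * st$N2[q, a] * adv
      }
    }
  }
  C1 <- .block_sparse(Cel, mesh$conn2, mesh$conn2, 9, 9, n2, n2)
  Matrix::bdiag(C1, C1)
}

# Wall Dirichlet helper: velocity DOF indices and values on given sides.
.vel_dirichlet <- function(mesh, sides, ux_vals, uy_vals) {
  dofs <- integer(0); vals <- numeric(0)
  for (k in seq_along(sides)) {
    ids <- mesh_boundary_nodes(mesh, sides[k])
    ux <- rep_len(ux_vals[[k]], length(ids))
    uy <- rep_len(uy_vals[[k]], length(ids))
    dofs <- c(dofs, ids, ids + mesh$n2)
    vals <- c(vals, ux, uy)
  }
  keep <- !duplicated(dofs)
  list(dofs = dofs[keep], vals = vals[keep])
}

#' Solve a steady incompressible flow problem
#'
#' Steady Stokes or Navier-Stokes (via Picard/Oseen iteration) on a fixed
#' mesh with velocity Dirichlet walls, optional pressure-like traction at
#' the axial ends, optional uniform body force, and a zero-mean pressure
#' gauge when no traction end is present.
#'
#' @param mesh a `quad_mesh`.
#' @param mu dynamic viscosity, Pa s.
#' @param rho fluid density, kg/m^3 (`0` solves pure Stokes: the convective
#'   term is dropped).
#' @param dirichlet named list mapping boundary sides to velocity values:
#'   each entry is `list(ux = ..., uy = ...)` with scalars or per-node
#'   vectors (node order as in [mesh_boundary_nodes()]).
#' @param traction named list mapping end sides (`endA`, `endB`) to the
#'   applied pressure `p1` (traction `-p1 n`); sides listed here are natural
#'   (stress) boundaries.  Use `p1 = 0` for a zero-traction open end.
#' @param body uniform body force `c(fx, fy)`, N/m^3.
#' @param picard maximum number of Picard iterations for the convective term
#'   (ignored when `rho = 0`); iteration stops when the relative velocity
#'   update drops below `tol`.
#' @param tol relative Picard tolerance.
#' @return list with nodal fields `ux`, `uy` (length `n2`), `p` (length
#'   `n1`), the Picard iteration count `iters` and relative update `delta`.
#' @export
solve_flow_steady <- function(mesh, mu, rho = 0, dirichlet = list(),
                              traction = NULL, body = c(0, 0),
                              picard = 10L, tol = 1e-10) {
  ops <- assemble_stokes(mesh, mu)
  n2 <- mesh$n2; n1 <- mesh$n1
  gauge <- is.null(traction) || length(traction) == 0
  nd <- 2L * n2 + n1 + (if (gauge) 1L else 0L)

  f <- numeric(nd)
  f[1:n2] <- body[1] * ops$bload
  f[n2 + 1:n2] <- body[2] * ops$bload
  if (!gauge) {
    for (side in names(traction)) {
      tl <- .traction_load(mesh, side, traction[[side]])
      f[1:n2] <- f[1:n2] + tl$fx
      f[n2 + 1:n2] <- f[n2 + 1:n2] + tl$fy
    }
  }
  sides <- names(dirichlet)
  bc <- .vel_dirichlet(mesh, sides,
                       lapply(dirichlet, `[[`, "ux"),
                       lapply(dirichlet, `[[`, "uy"))

  Zpp <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n1, n1))
  build <- function(C) {
    Ablk <- ops$A + if (is.null(C)) 0 else C
    K <- rbind(cbind(Ablk, -Matrix::t(ops$B)),
               cbind(-ops$B, Zpp))
    if (gauge) {
      gcol <- c(numeric(2 * n2), ops$gp)
      K <- rbind(cbind(K, gcol), c(gcol, 0))
    }
    K
  }

  uxp <- numeric(n2); uyp <- numeric(n2)
  iters <- 0L; delta <- NA_real_
  maxit <- if (rho == 0) 1L else max(1L, picard)
  for (it in seq_len(maxit)) {
    C <- if (rho > 0 && (it > 1 || any(bc$vals != 0)))
      assemble_convection(mesh, rho, uxp, uyp) else NULL
    K <- build(C)
    sys <- apply_dirichlet(K, f, bc$dofs, bc$vals)
    sol <- as.numeric(Matrix::solve(sys$K, sys$f))
    ux <- sol[1:n2]; uy <- sol[n2 + 1:n2]
    iters <- it
    nrm <- sqrt(sum(ux^2 + uy^2))
    delta <- if (nrm > 0) sqrt(sum((ux - uxp)^2 + (uy - uyp)^2)) / nrm else 0
    uxp <- ux; uyp <- uy
    if (rho == 0 || delta < tol) break
  }
  if (rho > 0 && delta > max(tol, 1e-8) && maxit > 1)
    warning(sprintf("Picard iteration stopped at %d with relative update %.2e",
                    iters, delta))
  list(ux = uxp, uy = uyp, p = sol[2 * n2 + 1:n1], iters = iters, delta = delta)
}

#' Divergence residual of a discrete velocity field
#'
#' Returns `max |B u|` over pressure test functions, normalised by the
#' domain measure: a direct check of the discrete incompressibility
#' constraint.
#'
#' @keywords internal
divergence_residual <- function(mesh, ux, uy, ops = NULL) {
  if (is.null(ops)) ops <- assemble_stokes(mesh, mu = 1)
  r <- as.numeric(ops$B %*% c(ux, uy))
  max(abs(r)) / mesh_volume(mesh)
}
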