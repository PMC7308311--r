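# Structured quadrilateral meshes with biquadratic (Q2) geometry/velocity
# nodes and bilinear (Q1) pressure nodes.  The logical grid has `nr` elements
# in the transverse direction (physical coordinate `x`: radius r for
# axisymmetric annuli, wall-normal coordinate for channels, in-plane x for
# cross-sections) and `nz` elements in the axial direction (`y`), optionally
# periodic in the axial direction.  Node coordinates may describe curvilinear
# (graded, deformed) geometry; all integrals use the isoparametric Q2 map.

GAUSS3_X <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
GAUSS3_W <- c(5, 8, 5) / 9

.shape_q2_1d <- function(x) cbind(x * (x - 1) / 2, 1 - x^2, x * (x + 1) / 2)
.dshape_q2_1d <- function(x) cbind(x - 0.5, -2 * x, x + 0.5)
.shape_q1_1d <- function(x) cbind((1 - x) / 2, (1 + x) / 2)
.dshape_q1_1d <- function(x) matrix(c(-0.5, 0.5), nrow = length(x), ncol = 2, byrow = TRUE)

# Tensor-product shape tables at the 3x3 Gauss points.
# Local ordering: a = (aj-1)*3 + ai (transverse index ai fastest).
.shape_tables <- local({
  qi <- rep(1:3, times = 3); qj <- rep(1:3, each = 3)
  xq <- GAUSS3_X[qi]; yq <- GAUSS3_X[qj]
  wq <- GAUSS3_W[qi] * GAUSS3_W[qj]
  n2x <- .shape_q2_1d(xq); d2x <- .dshape_q2_1d(xq)
  n2y <- .shape_q2_1d(yq); d2y <- .dshape_q2_1d(yq)
  n1x <- .shape_q1_1d(xq); d1x <- .dshape_q1_1d(xq)
  n1y <- .shape_q1_1d(yq); d1y <- .dshape_q1_1d(yq)
  N2 <- Dxi2 <- Deta2 <- matrix(0, 9, 9)
  for (a in 1:9) {
    ai <- (a - 1) %% 3 + 1; aj <- (a - 1) %/% 3 + 1
    N2[, a]    <- n2x[, ai] * n2y[, aj]
    Dxi2[, a]  <- d2x[, ai] * n2y[, aj]
    Deta2[, a] <- n2x[, ai] * d2y[, aj]
  }
  N1 <- Dxi1 <- Deta1 <- matrix(0, 9, 4)
  for (a in 1:4) {
    ai <- (a - 1) %% 2 + 1; aj <- (a - 1) %/% 2 + 1
    N1[, a]    <- n1x[, ai] * n1y[, aj]
    Dxi1[, a]  <- d1x[, ai] * n1y[, aj]
    Deta1[, a] <- n1x[, ai] * d1y[, aj]
  }
  list(w = wq, N2 = N2, Dxi2 = Dxi2, Deta2 = Deta2,
       N1 = N1, Dxi1 = Dxi1, Deta1 = Deta1)
})

#' Construct a structured quadrilateral mesh
#'
#' Builds the logical connectivity for an `nr` x `nz` element grid carrying
#' biquadratic geometry/velocity nodes and bilinear pressure nodes.
#'
#' @param xnode,ynode numeric matrices of Q2 node coordinates with dimensions
#'   `(2*nr+1) x (2*nz+1)`: transverse and axial physical coordinates.  For
#'   periodic meshes the last column repeats the first column's material
#'   nodes at the far axial end (same transverse coordinates, axial
#'   coordinate at the domain length); those nodes share degrees of freedom
#'   with the first column but keep their own geometric position.
#' @param nr,nz element counts in the transverse and axial directions.
#' @param periodic logical; identify the two axial ends (axially periodic
#'   domain).
#' @param axisym logical; if `TRUE` the transverse coordinate is the radius r
#'   and integrals carry the 2*pi*r measure of an axisymmetric volume.
#' @return an object of class `quad_mesh`.
#' @keywords internal
quad_mesh <- function(xnode, ynode, nr, nz, periodic = FALSE, axisym = FALSE) {
  Ni <- 2L * nr + 1L
  Njg <- 2L * nz + 1L                       # geometry columns (unwrapped)
  Nj <- if (periodic) 2L * nz else Njg      # DOF columns
  stopifnot(nrow(xnode) == Ni, ncol(xnode) == Njg,
            all(dim(xnode) == dim(ynode)))
  Npi <- nr + 1L
  Npj <- if (periodic) nz else nz + 1L
  ne <- nr * nz

  q2id <- function(i, j) (j - 1L) * Ni + i
  ei <- rep(seq_len(nr), times = nz); ej <- rep(seq_len(nz), each = nr)
  conn2 <- matrix(0L, ne, 9L)   # DOF connectivity (wraps when periodic)
  gconn <- matrix(0L, ne, 9L)   # geometry connectivity (never wraps)
  for (a in 1:9) {
    ai <- (a - 1L) %% 3L; aj <- (a - 1L) %/% 3L
    ii <- 2L * (ei - 1L) + 1L + ai
    jj <- 2L * (ej - 1L) + 1L + aj
    gconn[, a] <- q2id(ii, jj)
    if (periodic) jj <- (jj - 1L) %% Nj + 1L
    conn2[, a] <- q2id(ii, jj)
  }
  # Q1 connectivity: pressure nodes sit at Q2 corner nodes (odd i, odd j)
  q1id <- function(ip, jp) (jp - 1L) * Npi + ip
  conn1 <- matrix(0L, ne, 4L)
  for (a in 1:4) {
    ai <- (a - 1L) %% 2L; aj <- (a - 1L) %/% 2L
    ip <- ei + ai
    jp <- ej + aj
    if (periodic) jp <- (jp - 1L) %% Npj + 1L
    conn1[, a] <- q1id(ip, jp)
  }
  xg <- as.numeric(xnode); yg <- as.numeric(ynode)
  structure(list(
    nr = nr, nz = nz, Ni = Ni, Nj = Nj, Njg = Njg, Npi = Npi, Npj = Npj,
    ne = ne, n2 = Ni * Nj, n1 = Npi * Npj,
    x = xg[seq_len(Ni * Nj)], y = yg[seq_len(Ni * Nj)],
    xg = xg, yg = yg,
    conn2 = conn2, conn1 = conn1, gconn = gconn,
    periodic = periodic, axisym = axisym
  ), class = "quad_mesh")
}

#' Replace the node coordinates of a mesh (deformed configuration)
#'
#' @param mesh a `quad_mesh`.
#' @param xnode,ynode full geometry coordinate matrices/vectors of length
#'   `Ni * (2*nz+1)` (see [quad_mesh()]).
#' @keywords internal
mesh_set_coords <- function(mesh, xnode, ynode) {
  xg <- as.numeric(xnode); yg <- as.numeric(ynode)
  stopifnot(length(xg) == mesh$Ni * mesh$Njg, length(yg) == length(xg))
  mesh$xg <- xg; mesh$yg <- yg
  mesh$x <- xg[seq_len(mesh$Ni * mesh$Nj)]
  mesh$y <- yg[seq_len(mesh$Ni * mesh$Nj)]
  mesh
}

#' @export
print.quad_mesh <- function(x, ...) {
  cat(sprintf(
    "<quad_mesh> %d x %d elements (%s%s), %d velocity nodes, %d pressure nodes\n",
    x$nr, x$nz, if (x$axisym) "axisymmetric" else "planar",
    if (x$periodic) ", axially periodic" else "", x$n2, x$n1))
  invisible(x)
}

# Node-index helpers -------------------------------------------------------

.q2_grid_ids <- function(mesh, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(mesh$Ni)
  if (is.null(j)) j <- seq_len(mesh$Nj)
  as.integer(outer(i, (j - 1L) * mesh$Ni, `+`))
}

#' Boundary node indices of a structured mesh
#'
#' @param mesh a `quad_mesh`.
#' @param side one of `"inner"` (first transverse row), `"outer"` (last
#'   transverse row), `"endA"` (first axial column), `"endB"` (last axial
#'   column; unavailable on periodic meshes).
#' @return integer vector of Q2 node indices.
#' @keywords internal
mesh_boundary_nodes <- function(mesh, side) {
  switch(side,
    inner = .q2_grid_ids(mesh, i = 1L),
    outer = .q2_grid_ids(mesh, i = mesh$Ni),
    endA  = .q2_grid_ids(mesh, j = 1L),
    endB  = {
      if (mesh$periodic) stop("periodic mesh has no 'endB' boundary")
      .q2_grid_ids(mesh, j = mesh$Nj)
    },
    stop("unknown boundary side: ", side))
}

# Geometry at quadrature points --------------------------------------------
# Returns per-quadrature-point geometric data vectorised over elements:
# lists of length 9 (quadrature points), each entry with ne-vectors.
.mesh_quad_geom <- function(mesh, xn = mesh$xg, yn = mesh$yg) {
  st <- .shape_tables
  Xc <- matrix(xn[mesh$gconn], mesh$ne, 9)
  Yc <- matrix(yn[mesh$gconn], mesh$ne, 9)
  out <- vector("list", 9L)
  for (q in 1:9) {
    J11 <- Xc %*% st$Dxi2[q, ];  J12 <- Xc %*% st$Deta2[q, ]
    J21 <- Yc %*% st$Dxi2[q, ];  J22 <- Yc %*% st$Deta2[q, ]
    detJ <- as.numeric(J11 * J22 - J12 * J21)
    if (any(detJ <= 0)) stop("non-positive element Jacobian encountered")
    xq <- as.numeric(Xc %*% st$N2[q, ])
    w <- detJ * st$w[q] * (if (mesh$axisym) 2 * pi * xq else 1)
    inv <- 1 / detJ
    out[[q]] <- list(
      x = xq, w = w, detJ = detJ,
      dxidx =  as.numeric(J22) * inv, dxidy = -as.numeric(J12) * inv,
      detadx = -as.numeric(J21) * inv, detady = as.numeric(J11) * inv)
  }
  out
}

# Physical-space gradients of the Q2 basis at quadrature point q.
.q2_grads <- function(gq, q) {
  st <- .shape_tables
  g <- gq[[q]]
  gx <- outer(g$dxidx, st$Dxi2[q, ]) + outer(g$detadx, st$Deta2[q, ])
  gy <- outer(g$dxidy, st$Dxi2[q, ]) + outer(g$detady, st$Deta2[q, ])
  list(gx = gx, gy = gy)  # ne x 9 each
}

.q1_grads <- function(gq, q) {
  st <- .shape_tables
  g <- gq[[q]]
  gx <- outer(g$dxidx, st$Dxi1[q, ]) + outer(g$detadx, st$Deta1[q, ])
  gy <- outer(g$dxidy, st$Dxi1[q, ]) + outer(g$detady, st$Deta1[q, ])
  list(gx = gx, gy = gy)  # ne x 4 each
}

# Triplet accumulation helper: element-block matrix (ne x (na*nb)) -> sparse
.block_sparse <- function(kel, conn_row, conn_col, na, nb, nrow_, ncol_) {
  ii <- conn_row[, rep(seq_len(na), times = nb)]
  jj <- conn_col[, rep(seq_len(nb), each = na)]
  Matrix::sparseMatrix(i = as.integer(ii), j = as.integer(jj),
                       x = as.numeric(kel), dims = c(nrow_, ncol_))
}

#' Assemble scalar Laplace and mass operators on a mesh
#'
#' Stiffness `K = integral( grad(u) . grad(v) )` and mass
#' `M = integral(u v)` for a scalar field on Q2 nodes, plus the domain
#' measure.  On axisymmetric meshes the gradient is the (r,z)-plane gradient
#' of a scalar and the measure carries `2 pi r` (used for axial Poiseuille
#' flow and for mesh-motion components the measure is taken planar, see
#' `weight`).
#'
#' @param mesh a `quad_mesh`.
#' @param weight `"auto"` uses the mesh's natural measure; `"planar"` forces
#'   the planar measure (used for the mesh-motion Laplace problem, solved in
#'   the 2D computational domain).
#' @return list with sparse `K`, `M`, scalar `area` (domain measure) and the
#'   load vector `b1 = integral(v)`.
#' @keywords internal
assemble_scalar <- function(mesh, weight = c("auto", "planar")) {
  weight <- match.arg(weight)
  st <- .shape_tables
  planar <- weight == "planar" && mesh$axisym
  gq <- .mesh_quad_geom(mesh)
  ne <- mesh$ne
  Kel <- matrix(0, ne, 81); Mel <- matrix(0, ne, 81)
  b1 <- matrix(0, ne, 9)
  for (q in 1:9) {
    g <- .q2_grads(gq, q)
    w <- if (planar) gq[[q]]$detJ * st$w[q] else gq[[q]]$w
    for (a in 1:9) for (b in 1:9) {
      idx <- (b - 1) * 9 + a
      Kel[, idx] <- Kel[, idx] + w * (g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b])
      Mel[, idx] <- Mel[, idx] + w * st$N2[q, a] * st$N2[q, b]
    }
    b1 <- b1 + w * matrix(st$N2[q, ], ne, 9, byrow = TRUE)
  }
  K <- .block_sparse(Kel, mesh$conn2, mesh$conn2, 9, 9, mesh$n2, mesh$n2)
  M <- .block_sparse(Mel, mesh$conn2, mesh$conn2, 9, 9, mesh$n2, mesh$n2)
  acc <- rowsum(as.numeric(b1), as.integer(mesh$conn2))
  bv <- numeric(mesh$n2)
  bv[as.integer(rownames(acc))] <- acc
  list(K = K, M = M, area = sum(vapply(gq, function(g) sum(g$w), 0)), b1 = bv)
}

#' Impose Dirichlet values on a sparse linear system
#'
#' Standard row/column elimination with lifting: modifies `K x = f` so the
#' solution satisfies `x[dofs] = vals` exactly.
#'
#' @keywords internal
apply_dirichlet <- function(K, f, dofs, vals) {
  if (length(dofs) == 0) return(list(K = K, f = f))
  stopifnot(length(vals) == length(dofs) || length(vals) == 1L)
  vals <- rep_len(vals, length(dofs))
  xlift <- numeric(nrow(K)); xlift[dofs] <- vals
  f <- f - as.numeric(K %*% xlift)
  n <- nrow(K)
  keep <- Matrix::Diagonal(n, x = as.numeric(!(seq_len(n) %in% dofs)))
  K <- keep %*% K %*% keep + Matrix::Diagonal(n, x = as.numeric(seq_len(n) %in% dofs))
  f[dofs] <- vals
  list(K = Matrix::drop0(K), f = f)
}

#' Evaluate a Q2 nodal field at logical coordinates
#'
#' Logical coordinates `(s, t)` live on the unit square: `s` in [0,1] across
#' the transverse direction, `t` in [0,1] along the axial direction (for
#' periodic meshes `t` wraps).  Meshes produced by the package's generators
#' place elements uniformly in logical space, so the same `(s, t)` addresses
#' the same material point across refinement levels.
#'
#' @param mesh a `quad_mesh`.
#' @param nodal numeric vector of length `mesh$n2` (Q2 field) or `mesh$n1`
#'   (Q1 field, detected by length).
#' @param s,t numeric vectors of logical coordinates (recycled to common
#'   length).
#' @return numeric vector of field values.
#' @keywords internal
fem_eval_logical <- function(mesh, nodal, s, t) {
  n <- max(length(s), length(t))
  s <- rep_len(s, n); t <- rep_len(t, n)
  if (mesh$periodic) t <- t %% 1
  s <- pmin(pmax(s, 0), 1)
  t <- pmin(pmax(t, 0), 1 - 1e-15)
  ei <- pmin(pmax(ceiling(s * mesh$nr), 1L), mesh$nr)
  ej <- pmin(pmax(ceiling(t * mesh$nz), 1L), mesh$nz)
  xi <- 2 * (s * mesh$nr - (ei - 1)) - 1
  eta <- 2 * (t * mesh$nz - (ej - 1)) - 1
  el <- (ej - 1L) * mesh$nr + ei
  q1 <- length(nodal) == mesh$n1
  if (q1) {
    nx <- .shape_q1_1d(xi); ny <- .shape_q1_1d(eta)
    conn <- mesh$conn1[el, , drop = FALSE]
    out <- numeric(n)
    for (a in 1:4) {
      ai <- (a - 1) %% 2 + 1; aj <- (a - 1) %/% 2 + 1
      out <- out + nodal[conn[, a]] * nx[, ai] * ny[, aj]
    }
  } else {
    stopifnot(length(nodal) == mesh$n2)
    nx <- .shape_q2_1d(xi); ny <- .shape_q2_1d(eta)
    conn <- mesh$conn2[el, , drop = FALSE]
    out <- numeric(n)
    for (a in 1:9) {
      ai <- (a - 1) %% 3 + 1; aj <- (a - 1) %/% 3 + 1
      out <- out + nodal[conn[, a]] * nx[, ai] * ny[, aj]
    }
  }
  out
}

#' Locate physical points in a mesh and evaluate a nodal field
#'
#' Newton inversion of the isoparametric Q2 map, with a nearest-element
#' search.  Intended for a small number of probe points.
#'
#' @param mesh a `quad_mesh`.
#' @param nodal Q2 nodal field (length `mesh$n2`).
#' @param px,py physical coordinates of the probe points.
#' @return numeric vector of interpolated values; `NA` for points not found
#'   inside the mesh.
#' @keywords internal
fem_eval_points <- function(mesh, nodal, px, py) {
  n <- max(length(px), length(py))
  px <- rep_len(px, n); py <- rep_len(py, n)
  st <- .shape_tables
  Xc <- matrix(mesh$xg[mesh$gconn], mesh$ne, 9)
  Yc <- matrix(mesh$yg[mesh$gconn], mesh$ne, 9)
  cx <- Xc[, 5]; cy <- Yc[, 5]  # element centers (local (0,0) node)
  out <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    ord <- order((cx - px[k])^2 + (cy - py[k])^2)[seq_len(min(9L, mesh$ne))]
    for (el in ord) {
      xi <- c(0, 0)
      ok <- FALSE
      for (it in 1:30) {
        nxv <- .shape_q2_1d(xi[1]); nyv <- .shape_q2_1d(xi[2])
        dxv <- .dshape_q2_1d(xi[1]); dyv <- .dshape_q2_1d(xi[2])
        N <- as.numeric(outer(nxv[1, ], nyv[1, ]))
        Dxi <- as.numeric(outer(dxv[1, ], nyv[1, ]))
        Deta <- as.numeric(outer(nxv[1, ], dyv[1, ]))
        r <- c(sum(Xc[el, ] * N) - px[k], sum(Yc[el, ] * N) - py[k])
        J <- rbind(c(sum(Xc[el, ] * Dxi), sum(Xc[el, ] * Deta)),
                   c(sum(Yc[el, ] * Dxi), sum(Yc[el, ] * Deta)))
        step <- solve(J, r)
        xi <- xi - step
        if (sum(abs(step)) < 1e-13) { ok <- TRUE; break }
        if (any(abs(xi) > 3)) break
      }
      if (ok && all(abs(xi) <= 1 + 1e-8)) {
        nxv <- .shape_q2_1d(xi[1]); nyv <- .shape_q2_1d(xi[2])
        N <- as.numeric(outer(nxv[1, ], nyv[1, ]))
        out[k] <- sum(nodal[mesh$conn2[el, ]] * N)
        break
      }
    }
  }
  out
}

#' Integrate fields over the mesh
#'
#' Computes `integral(f)` for one or several Q2/Q1 nodal fields using the
#' mesh's quadrature and natural measure.
#'
#' @keywords internal
mesh_integrate <- function(mesh, nodal) {
  st <- .shape_tables
  gq <- .mesh_quad_geom(mesh)
  q1 <- length(nodal) == mesh$n1
  conn <- if (q1) mesh$conn1 else mesh$conn2
  Ntab <- if (q1) st$N1 else st$N2
  vals <- matrix(nodal[conn], mesh$ne, ncol(conn))
  tot <- 0
  for (q in 1:9) tot <- tot + sum(gq[[q]]$w * (vals %*% Ntab[q, ]))
  tot
}

# Boundary face quadrature --------------------------------------------------
# Returns, for a given logical side, per-face quadrature data: points,
# weights (including the axisymmetric 2*pi*r measure), outward unit normals,
# and the Q2 node indices with 1D quadratic shape values.
.mesh_face_quad <- function(mesh, side) {
  horiz <- side %in% c("inner", "outer")   # face runs along axial direction
  if (side == "endB" && mesh$periodic) stop("periodic mesh has no 'endB'")
  nface <- if (horiz) mesh$nz else mesh$nr
  gid <- function(i, j) (j - 1L) * mesh$Ni + i
  # 3 nodes per face: DOF indices (wrap) and geometry indices (no wrap)
  idx <- gidx <- matrix(0L, nface, 3)
  for (f in seq_len(nface)) {
    if (horiz) {
      i <- if (side == "inner") 1L else mesh$Ni
      j <- 2L * (f - 1L) + 1:3
      gidx[f, ] <- gid(i, j)
      if (mesh$periodic) j <- (j - 1L) %% mesh$Nj + 1L
      idx[f, ] <- .q2_grid_ids(mesh, i = i, j = j)
    } else {
      j <- if (side == "endA") 1L else mesh$Nj
      i <- 2L * (f - 1L) + 1:3
      gidx[f, ] <- gid(i, j)
      idx[f, ] <- .q2_grid_ids(mesh, i = i, j = j)
    }
  }
  N <- .shape_q2_1d(GAUSS3_X)   # 3 quad pts x 3 nodes
  D <- .dshape_q2_1d(GAUSS3_X)
  Xf <- matrix(mesh$xg[gidx], nface, 3)
  Yf <- matrix(mesh$yg[gidx], nface, 3)
  # per-face interior reference points (adjacent node row) to orient normals
  gin <- gidx
  if (horiz) {
    gin[] <- gidx + (if (side == "inner") 1L else -1L)
  } else {
    gin[] <- gidx + (if (side == "endA") mesh$Ni else -mesh$Ni)
  }
  Xi <- matrix(mesh$xg[gin], nface, 3)
  Yi <- matrix(mesh$yg[gin], nface, 3)
  out <- vector("list", 3L)
  for (q in 1:3) {
    xq <- Xf %*% N[q, ]; yq <- Yf %*% N[q, ]
    tx <- Xf %*% D[q, ]; ty <- Yf %*% D[q, ]
    ds <- sqrt(tx^2 + ty^2)
    nx <- ty / ds; ny <- -tx / ds
    xin <- Xi %*% N[q, ]; yin <- Yi %*% N[q, ]
    # orient outward (away from domain interior)
    flip <- (nx * (xin - xq) + ny * (yin - yq)) > 0
    nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
    w <- as.numeric(ds) * GAUSS3_W[q] * (if (mesh$axisym) 2 * pi * as.numeric(xq) else 1)
    out[[q]] <- list(x = as.numeric(xq), y = as.numeric(yq), w = w,
                     nx = as.numeric(nx), ny = as.numeric(ny), shp = N[q, ])
  }
  list(idx = idx, quad = out)
}

#' Net volumetric flux of a velocity field through a boundary side
#'
#' @param mesh a `quad_mesh`.
#' @param ux,uy Q2 nodal velocity components.
#' @param side boundary side name (see [mesh_boundary_nodes()]).
#' @return scalar flux `integral(u . n ds)` with outward normal.
#' @keywords internal
boundary_flux <- function(mesh, ux, uy, side) {
  fq <- .mesh_face_quad(mesh, side)
  Uf <- matrix(ux[fq$idx], nrow(fq$idx), 3)
  Vf <- matrix(uy[fq$idx], nrow(fq$idx), 3)
  tot <- 0
  for (q in 1:3) {
    g <- fq$quad[[q]]
    uq <- Uf %*% g$shp; vq <- Vf %*% g$shp
    tot <- tot + sum(g$w * (as.numeric(uq) * g$nx + as.numeric(vq) * g$ny))
  }
  tot
}

# Load vector from a prescribed traction t = -p1 * n on a boundary side:
# adds integral( t . v ds ) for both velocity components.
.traction_load <- function(mesh, side, p1) {
  fq <- .mesh_face_quad(mesh, side)
  fx <- numeric(mesh$n2); fy <- numeric(mesh$n2)
  for (q in 1:3) {
    g <- fq$quad[[q]]
    for (a in 1:3) {
      w <- g$w * g$shp[a]
      ids <- fq$idx[, a]
      fx[ids] <- fx[ids] + (-p1) * g$nx * w
      fy[ids] <- fy[ids] + (-p1) * g$ny * w
    }
  }
  list(fx = fx, fy = fy)
}

#' Total measure (volume/area) of the meshed domain
#' @keywords internal
mesh_volume <- function(mesh) {
  gq <- .mesh_quad_geom(mesh)
  sum(vapply(gq, function(g) sum(g$w), 0))
}
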