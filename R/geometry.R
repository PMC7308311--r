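# Solver domains: the axisymmetric annulus (PVS idealised as a concentric
# annular gap around the artery) and the realistic two-lobed cross-section
# bounded by the arterial circle and an outer ellipse, with fillet arcs
# smoothing the junctions.  All lengths are SI metres.

# Radial grading: smooth map of [0,1] clustering nodes at both walls.
# Element-size ratio between largest (mid-gap) and smallest (wall) element is
# (1+beta)/(1-beta); beta = 0.5 gives ratio 3.
.grade_both <- function(s, beta = 0.5) s - beta * sin(2 * pi * s) / (2 * pi)

#' Annular PVS domain
#'
#' @param R1 inner (arterial) radius, m.
#' @param R2 outer radius, m.
#' @param L axial length, m (one wavelength for the periodic peristalsis
#'   model; the MCA length for the short-domain model).
#' @param end_condition `"periodic"` or `"traction"`.
#' @return an `annulus_domain` object.
#' @export
annulus_domain <- function(R1, R2, L, end_condition = c("periodic", "traction")) {
  end_condition <- match.arg(end_condition)
  if (!is.finite(R1) || R1 <= 0) stop("R1 must be positive (got ", R1, ")")
  if (!is.finite(R2) || R2 <= 0) stop("R2 must be positive (got ", R2, ")")
  if (R1 >= R2) stop("R1 must be smaller than R2 (got R1 = ", R1, ", R2 = ", R2, ")")
  if (!is.finite(L) || L <= 0) stop("L must be positive (got ", L, ")")
  structure(list(R1 = R1, R2 = R2, L = L, end_condition = end_condition),
            class = "annulus_domain")
}

#' Build a graded structured mesh on an annulus
#'
#' The mesh has `5*m` radial and `50*m` axial elements (the production
#' resolution corresponds to `m = 2`: 10 x 100), with radial grading towards
#' both walls (largest-to-smallest element ratio 3).  Boundary sides are
#' tagged `inner`, `outer`, `endA`, `endB` (the ends are identified when
#' `end_condition = "periodic"`).
#'
#' @inheritParams annulus_domain
#' @param m refinement factor (positive integer).
#' @return list with elements `domain` (an [annulus_domain()]) and `mesh`
#'   (a `quad_mesh`).
#' @export
build_annulus <- function(R1, R2, L, end_condition = c("periodic", "traction"),
                          m = 2L) {
  domain <- annulus_domain(R1, R2, L, end_condition)
  if (!is.finite(m) || m < 1 || m != round(m)) stop("m must be a positive integer (got ", m, ")")
  mesh <- mesh_annulus(domain, m = m)
  list(domain = domain, mesh = mesh)
}

#' @rdname build_annulus
#' @param domain an `annulus_domain`.
#' @param nr,nz optional explicit element counts (default `5*m`, `50*m`).
#' @export
mesh_annulus <- function(domain, m = 2L, nr = NULL, nz = NULL) {
  stopifnot(inherits(domain, "annulus_domain"))
  if (is.null(nr)) nr <- 5L * as.integer(m)
  if (is.null(nz)) nz <- 50L * as.integer(m)
  periodic <- domain$end_condition == "periodic"
  Ni <- 2L * nr + 1L
  Njg <- 2L * nz + 1L
  s <- seq(0, 1, length.out = Ni)
  r <- domain$R1 + (domain$R2 - domain$R1) * .grade_both(s)
  z <- seq(0, 1, length.out = Njg) * domain$L
  X <- matrix(r, Ni, Njg)
  Y <- matrix(z, Ni, Njg, byrow = TRUE)
  quad_mesh(X, Y, nr, nz, periodic = periodic, axisym = TRUE)
}

# Lobed cross-section --------------------------------------------------------

.ellipse_point <- function(a, b, phi) cbind(a * cos(phi), b * sin(phi))

# signed distance helper: closest point on ellipse (a,b) to p = c(x, y),
# returns list(phi, d)
.ellipse_closest <- function(a, b, p) {
  f <- function(phi) {
    e <- c(a * cos(phi), b * sin(phi))
    t <- c(-a * sin(phi), b * cos(phi))
    sum((p - e) * t)
  }
  phi0 <- atan2(p[2] / b, p[1] / a)
  lo <- phi0 - 1; hi <- phi0 + 1
  while (f(lo) * f(hi) > 0) { lo <- lo - 0.5; hi <- hi + 0.5 }
  phi <- stats::uniroot(f, c(lo, hi), tol = 1e-15)$root
  e <- c(a * cos(phi), b * sin(phi))
  list(phi = phi, d = sqrt(sum((p - e)^2)), pt = e)
}

#' Two-lobed PVS cross-section
#'
#' The perivascular space around a pial artery: the region inside an outer
#' ellipse (semi-axes `a_out` along x, `b_out` along y) and outside the
#' arterial circle (radius `R1`).  Because `b_out < R1 < a_out`, the circle
#' and ellipse intersect in four points and the fluid domain splits into two
#' mirror-image lobes on the major axis.  The four circle/ellipse junctions
#' are smoothed with fillet arcs of radius `fillet_r`; boundary segments are
#' labelled `inner_wall` (circular arcs, facing the artery), `outer_wall`
#' (elliptic arcs, facing brain/SAS) and `transition` (fillet arcs).
#'
#' @param R1 arterial (inner circle) radius, m.
#' @param a_out,b_out outer-ellipse semi-axes, m; defaults follow the PVS
#'   geometry: `a_out = R2 = 70/30 * R1`, `b_out = 0.8 * R1`.
#' @param fillet_r fillet radius, m; default `0.08 * R1`.
#' @return a `lobed_section` object describing the right-hand lobe (the left
#'   lobe is its mirror image across the minor axis).
#' @export
lobed_cross_section <- function(R1, a_out = 7 / 3 * R1, b_out = 0.8 * R1,
                                fillet_r = 0.08 * R1) {
  if (!is.finite(R1) || R1 <= 0) stop("R1 must be positive (got ", R1, ")")
  if (b_out >= R1) stop("b_out must be smaller than R1 for the circle and ellipse to intersect (got b_out = ",
                        b_out, ", R1 = ", R1, ")")
  if (a_out <= R1) stop("a_out must exceed R1 for the circle and ellipse to intersect (got a_out = ",
                        a_out, ", R1 = ", R1, ")")
  if (fillet_r < 0) stop("fillet_r must be nonnegative (got ", fillet_r, ")")
  a <- a_out; b <- b_out
  xi2 <- (1 - R1^2 / b^2) / (1 / a^2 - 1 / b^2)
  xi <- sqrt(xi2); yi <- sqrt(R1^2 - xi2)
  theta_i <- atan2(yi, xi)              # polar angle of the sharp corner
  phi_i <- acos(xi / a)                 # ellipse parametric angle of corner
  if (fillet_r == 0) {
    theta_f <- theta_i; phi_f <- phi_i
    fillet_center <- R1 * c(cos(theta_i), sin(theta_i))
    tc <- fillet_center; te <- .ellipse_point(a, b, phi_i)[1, ]
  } else {
    # fillet circle: tangent externally to the arterial circle (center at
    # distance R1 + rho from origin) and internally to the ellipse
    g <- function(th) {
      p <- (R1 + fillet_r) * c(cos(th), sin(th))
      .ellipse_closest(a, b, p)$d - fillet_r
    }
    lo <- 1e-3; hi <- theta_i - 1e-9
    if (g(lo) * g(hi) > 0) stop("fillet_r too large: fillet does not fit in the lobe corner")
    theta_f <- stats::uniroot(g, c(lo, hi), tol = 1e-15)$root
    fillet_center <- (R1 + fillet_r) * c(cos(theta_f), sin(theta_f))
    ec <- .ellipse_closest(a, b, fillet_center)
    phi_f <- ec$phi
    tc <- R1 * c(cos(theta_f), sin(theta_f))  # tangency on circle
    te <- ec$pt                                # tangency on ellipse
    if (phi_f >= phi_i || theta_f >= theta_i)
      stop("fillet_r too large: fillet consumes the lobe corner")
  }
  structure(list(
    R1 = R1, a_out = a, b_out = b, fillet_r = fillet_r,
    corner = c(xi, yi), theta_i = theta_i, phi_i = phi_i,
    theta_f = theta_f, phi_f = phi_f,
    fillet_center = fillet_center, tangent_circle = tc, tangent_ellipse = te
  ), class = "lobed_section")
}

#' @export
print.lobed_section <- function(x, ...) {
  cat(sprintf(
    "<lobed_section> R1 = %.3g m, ellipse %.3g x %.3g m, fillet %.3g m\n",
    x$R1, x$a_out, x$b_out, x$fillet_r))
  invisible(x)
}

#' Analytic lobe area for a sharp-cornered (zero-fillet) section
#'
#' Closed form from circle/ellipse sector geometry: the single-lobe area is
#' `a*b*phi_i - R1^2*theta_i` with `phi_i` the ellipse parametric angle and
#' `theta_i` the polar angle of the intersection point.
#'
#' @param section a `lobed_section` (the fillet radius is ignored).
#' @return single-lobe area, m^2.
#' @export
lobe_area_analytic <- function(section) {
  stopifnot(inherits(section, "lobed_section"))
  with(section, a_out * b_out * phi_i - R1^2 * theta_i)
}

# Boundary curves of the right lobe, each parameterised on [0,1]:
#  inner(t):  circle arc  theta in [-theta_f, +theta_f]
#  outer(t):  ellipse arc phi   in [-phi_f,  +phi_f]
#  bottom(s): fillet arc at the lower corner, from circle to ellipse tangency
#  top(s):    fillet arc at the upper corner
.lobe_edges <- function(sec) {
  inner <- function(t) {
    th <- -sec$theta_f + 2 * sec$theta_f * t
    cbind(sec$R1 * cos(th), sec$R1 * sin(th))
  }
  outer_ <- function(t) {
    ph <- -sec$phi_f + 2 * sec$phi_f * t
    .ellipse_point(sec$a_out, sec$b_out, ph)
  }
  fillet <- function(s, upper) {
    if (sec$fillet_r == 0) {
      pt <- sec$corner * c(1, if (upper) 1 else -1)
      return(matrix(rep(pt, each = length(s)), ncol = 2))
    }
    cen <- sec$fillet_center
    a1 <- atan2(sec$tangent_circle[2] - cen[2], sec$tangent_circle[1] - cen[1])
    a2 <- atan2(sec$tangent_ellipse[2] - cen[2], sec$tangent_ellipse[1] - cen[1])
    # shortest arc from circle tangency to ellipse tangency
    da <- ((a2 - a1 + pi) %% (2 * pi)) - pi
    ang <- a1 + s * da
    p <- cbind(cen[1] + sec$fillet_r * cos(ang), cen[2] + sec$fillet_r * sin(ang))
    if (!upper) p[, 2] <- -p[, 2]
    p
  }
  list(inner = inner, outer = outer_,
       bottom = function(s) fillet(s, upper = FALSE),
       top = function(s) fillet(s, upper = TRUE))
}

#' Mesh the two-lobed cross-section
#'
#' Builds a boundary-conforming structured mesh on the right-hand lobe by
#' transfinite (Coons) interpolation between the inner circular arc, the
#' outer elliptic arc and the two fillet arcs.  The transverse logical
#' direction runs from the inner wall (`side = "inner"`) to the outer wall
#' (`"outer"`); the sides `endA`/`endB` are the lower/upper fillet arcs
#' (`transition` region).  The full cross-section is this lobe plus its
#' mirror image; section-integrated quantities (area, flow rate) are twice
#' the lobe values.
#'
#' @param R1,a_out,b_out,fillet_r geometry, see [lobed_cross_section()].
#' @param target_edge_length requested element edge length, m; sets the
#'   element counts from the arc lengths.
#' @return list with `section` (a `lobed_section`) and `mesh` (a planar
#'   `quad_mesh` covering the right lobe).
#' @export
build_lobed_section <- function(R1, a_out = 7 / 3 * R1, b_out = 0.8 * R1,
                                fillet_r = 0.08 * R1,
                                target_edge_length = (a_out - R1) / 12) {
  sec <- lobed_cross_section(R1, a_out, b_out, fillet_r)
  edges <- .lobe_edges(sec)
  gap <- sec$a_out - sec$R1
  arc_in <- 2 * sec$theta_f * sec$R1
  nr <- max(4L, ceiling(gap / target_edge_length))
  nz <- max(6L, ceiling(arc_in / target_edge_length))
  Ni <- 2L * nr + 1L; Nj <- 2L * nz + 1L
  s <- seq(0, 1, length.out = Ni)     # inner -> outer
  t <- seq(0, 1, length.out = Nj)     # lower corner -> upper corner
  Pi_ <- edges$inner(t); Po <- edges$outer(t)
  Pb <- edges$bottom(s); Pt <- edges$top(s)
  C00 <- Pi_[1, ]; C01 <- Pi_[Nj, ]; C10 <- Po[1, ]; C11 <- Po[Nj, ]
  X <- Y <- matrix(0, Ni, Nj)
  for (k in seq_len(Nj)) {
    tk <- t[k]
    X[, k] <- (1 - s) * Pi_[k, 1] + s * Po[k, 1] +
      (1 - tk) * Pb[, 1] + tk * Pt[, 1] -
      ((1 - s) * (1 - tk) * C00[1] + (1 - s) * tk * C01[1] +
         s * (1 - tk) * C10[1] + s * tk * C11[1])
    Y[, k] <- (1 - s) * Pi_[k, 2] + s * Po[k, 2] +
      (1 - tk) * Pb[, 2] + tk * Pt[, 2] -
      ((1 - s) * (1 - tk) * C00[2] + (1 - s) * tk * C01[2] +
         s * (1 - tk) * C10[2] + s * tk * C11[2])
  }
  mesh <- quad_mesh(X, Y, nr, nz, periodic = FALSE, axisym = FALSE)
  list(section = sec, mesh = mesh)
}

#' Mid-gap probe point of a PVS geometry
#'
#' The point midway between the inner and outer walls: radius
#' `(R1 + R2) / 2` for the annulus; for the lobed section the point on the
#' major axis at `x = (R1 + a_out) / 2`, `y = 0` (inside the right lobe).
#'
#' @param geom an `annulus_domain` or `lobed_section`.
#' @return for an annulus, a list with `r`; for a lobed section, a list with
#'   `x` and `y`.
#' @export
point_midgap <- function(geom) {
  if (inherits(geom, "annulus_domain")) {
    list(r = (geom$R1 + geom$R2) / 2)
  } else if (inherits(geom, "lobed_section")) {
    list(x = (geom$R1 + geom$a_out) / 2, y = 0)
  } else stop("point_midgap: unsupported geometry of class ", class(geom)[1])
}

#' Build a planar channel mesh
#'
#' A 2D channel of height `h` (transverse coordinate, walls at 0 and `h`) and
#' length `L` (axial coordinate), with optional transverse grading towards
#' both walls.
#'
#' @param h channel height, m.
#' @param L channel length, m.
#' @param nr,nz element counts across and along the channel.
#' @param periodic axially periodic ends.
#' @param graded cluster nodes at the walls (ratio-3 grading).
#' @return a planar `quad_mesh`.
#' @export
mesh_channel <- function(h, L, nr = 8L, nz = 24L, periodic = FALSE, graded = TRUE) {
  if (h <= 0) stop("h must be positive (got ", h, ")")
  if (L <= 0) stop("L must be positive (got ", L, ")")
  Ni <- 2L * nr + 1L
  Njg <- 2L * nz + 1L
  s <- seq(0, 1, length.out = Ni)
  yv <- if (graded) h * .grade_both(s) else h * s
  X <- matrix(yv, Ni, Njg)
  Y <- matrix(seq(0, 1, length.out = Njg) * L, Ni, Njg, byrow = TRUE)
  quad_mesh(X, Y, nr, nz, periodic = periodic, axisym = FALSE)
}
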