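# Steady pressure-driven axial flow through PVS cross-sections: the
# closed-form hydraulic resistance of a concentric annulus, a numeric
# Poisson solver for arbitrary meshed sections (including the two-lobed
# geometry), and pipe-flow Reynolds/Peclet metrics.

MMHG_PA <- 133.322  # 1 mmHg in Pa

#' Hydraulic resistance of a concentric annulus
#'
#' Per-unit-length resistance of laminar axial flow in the annular gap
#' between radii `r1` and `r2`:
#' \deqn{R_{flow} = \frac{8\mu}{\pi}\left[r_2^4 - r_1^4 -
#'   \frac{(r_2^2-r_1^2)^2}{\ln(r_2/r_1)}\right]^{-1}}
#' so that the volumetric flow rate under an axial pressure gradient is
#' `Q = -(dp/dz) / R_flow`.  The limit `r1 = 0` is the circular-pipe
#' (Hagen-Poiseuille) resistance `8 mu / (pi r2^4)`.
#'
#' @param r1 inner radius, m (`0` gives the circular pipe limit).
#' @param r2 outer radius, m.
#' @param mu dynamic viscosity, Pa s.
#' @return resistance per unit length, Pa s / m^4.
#' @export
annular_resistance <- function(r1, r2, mu) {
  if (any(mu <= 0)) stop("mu must be positive (got ", mu, ")")
  if (any(r2 <= 0)) stop("r2 must be positive (got ", r2, ")")
  if (any(r1 < 0)) stop("r1 must be nonnegative (got ", r1, ")")
  if (any(r1 >= r2)) stop("r1 must be smaller than r2 (got r1 = ", r1,
                          ", r2 = ", r2, ")")
  bracket <- ifelse(r1 == 0, r2^4,
                    r2^4 - r1^4 - (r2^2 - r1^2)^2 / log(r2 / r1))
  (8 * mu / pi) / bracket
}

#' Solve steady axial Poiseuille flow on a meshed cross-section
#'
#' Solves `mu * laplacian(w) = dpdz` with no-slip (`w = 0`) on the walls for
#' the axial velocity `w(x, y)` of fully developed laminar flow.  On a
#' planar mesh (a true cross-section such as the lobed PVS) all four logical
#' sides are walls by default; on an axisymmetric annulus mesh the `inner`
#' and `outer` sides are walls and the formulation reduces to the radial
#' annular profile.
#'
#' @param mesh a `quad_mesh` of the cross-section.
#' @param mu dynamic viscosity, Pa s.
#' @param dpdz axial pressure gradient, Pa/m (negative drives `w > 0`).
#' @param wall_sides boundary sides held at `w = 0`.
#' @return list with `w` (Q2 nodal axial velocity), `Q` (volumetric flow
#'   rate through the meshed section; for an axisymmetric mesh the full
#'   annulus, for a single meshed lobe just that lobe), and `area`.
#' @export
solve_section_poiseuille <- function(mesh, mu, dpdz,
                                     wall_sides = NULL) {
  if (mu <= 0) stop("mu must be positive (got ", mu, ")")
  if (is.null(wall_sides)) {
    wall_sides <- if (mesh$periodic) c("inner", "outer")
                  else c("inner", "outer", "endA", "endB")
  }
  sc <- assemble_scalar(mesh)
  # weak form: mu * integral(grad w . grad v) = -dpdz * integral(v)
  f <- -dpdz * sc$b1
  dofs <- unique(unlist(lapply(wall_sides, mesh_boundary_nodes, mesh = mesh)))
  sys <- apply_dirichlet(mu * sc$K, f, dofs, 0)
  w <- as.numeric(Matrix::solve(sys$K, sys$f))
  Q <- mesh_integrate(mesh, w)
  if (mesh$axisym && mesh$periodic) {
    # axisymmetric formulation integrates over the axial extent as well
    L <- diff(range(mesh$yg))
    Q <- Q / L
  }
  list(w = w, Q = Q, area = sc$area)
}

#' Steady flow through the two-lobed PVS cross-section
#'
#' Convenience wrapper: meshes the lobed section, solves the axial Poiseuille
#' problem on one lobe and reports full-section quantities (both mirror-image
#' lobes) plus the mid-gap speed at the probe point on the major axis.
#'
#' @param built output of [build_lobed_section()].
#' @param mu dynamic viscosity, Pa s.
#' @param dpdz axial pressure gradient, Pa/m (negative drives positive flow);
#'   alternatively give `dp` and `L` to set `dpdz = -dp / L`.
#' @param dp,L pressure difference (Pa) driving flow down a segment of
#'   length `L` (m); used when `dpdz` is missing.
#' @return list with `Q` (full-section flow rate, m^3/s), `v_mid` (mid-gap
#'   speed at the probe point, m/s), `area`, `perimeter` (full section),
#'   `w`, `mesh`.
#' @export
lobed_poiseuille <- function(built, mu, dpdz = NULL, dp = NULL, L = NULL) {
  stopifnot(inherits(built$section, "lobed_section"))
  if (is.null(dpdz)) {
    if (is.null(dp) || is.null(L)) stop("give either dpdz or both dp and L")
    dpdz <- -dp / L
  }
  sol <- solve_section_poiseuille(built$mesh, mu, dpdz)
  pm <- point_midgap(built$section)
  v_mid <- fem_eval_points(built$mesh, sol$w, pm$x, pm$y)
  per <- section_perimeter(built$mesh)
  list(Q = 2 * sol$Q, v_mid = as.numeric(v_mid), area = 2 * sol$area,
       perimeter = 2 * per, w = sol$w, mesh = built$mesh)
}

#' Wetted perimeter of a meshed planar section
#' @keywords internal
section_perimeter <- function(mesh) {
  sides <- c("inner", "outer", if (!mesh$periodic) c("endA", "endB"))
  tot <- 0
  for (s in sides) {
    fq <- .mesh_face_quad(mesh, s)
    tot <- tot + sum(vapply(fq$quad, function(g) sum(g$w), 0))
  }
  tot
}

#' Pipe-flow Reynolds and Peclet numbers
#'
#' `D_h = 4 A / P`; `Re = rho * Q * D_h / (mu * A)`;
#' `Pe = v_ave * D_h / D` with `v_ave` the mid-gap downstream speed.
#'
#' @param Q volumetric flow rate, m^3/s.
#' @param v_ave mid-gap downstream speed, m/s.
#' @param area cross-section area, m^2.
#' @param perimeter wetted perimeter, m.
#' @param rho fluid density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param D diffusion coefficient, m^2/s (default: amyloid-beta in water,
#'   1.4e-6 cm^2/s).
#' @return list with `D_h`, `Re`, `Pe`, and the inputs.
#' @export
compute_re_pe <- function(Q, v_ave, area, perimeter, rho = 1000, mu = 1e-3,
                          D = 1.4e-10) {
  if (perimeter <= 0) stop("perimeter must be positive (got ", perimeter, ")")
  if (area <= 0) stop("area must be positive (got ", area, ")")
  D_h <- 4 * area / perimeter
  list(D_h = D_h,
       Re = rho * abs(Q) * D_h / (mu * area),
       Pe = abs(v_ave) * D_h / D,
       Q = Q, v_ave = v_ave, area = area, perimeter = perimeter, D = D)
}
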