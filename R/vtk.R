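# Minimal legacy-VTK (ASCII) export of structured quad meshes and nodal
# fields, for inspection of field snapshots in ParaView and friends.

#' Write a mesh with nodal fields to a legacy VTK file
#'
#' Exports the bilinear (corner-node) skeleton of the mesh as
#' `VTK_QUAD` cells with point data.  Q2-length fields are sampled at the
#' corner nodes; Q1-length fields are written as is.  Vector pairs can be
#' passed as a two-column matrix.
#'
#' @param mesh a `quad_mesh`.
#' @param file output path.
#' @param point_data named list of nodal fields (numeric vectors of length
#'   `n2` or `n1`, or matrices with one column per component).
#' @param title dataset title line.
#' @return the file path, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list(), title = "pvsflow") {
  # corner (Q1) points in DOF numbering
  iodd <- seq(1L, mesh$Ni, by = 2L)
  jodd <- seq(1L, mesh$Nj, by = 2L)
  cor2 <- as.integer(outer(iodd, (jodd - 1L) * mesh$Ni, `+`))  # Q2 ids
  np <- length(cor2)
  px <- mesh$x[cor2]; py <- mesh$y[cor2]
  # cells: use the Q1 connectivity (already wraps on periodic meshes);
  # VTK corner order is counter-clockwise: local Q1 nodes 1,2,4,3
  cells <- mesh$conn1[, c(1, 2, 4, 3), drop = FALSE] - 1L
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", np)), con)
  writeLines(sprintf("%.10g %.10g 0", px, py), con)
  ne <- nrow(cells)
  writeLines(sprintf("CELLS %d %d", ne, 5L * ne), con)
  writeLines(paste(4L, cells[, 1], cells[, 2], cells[, 3], cells[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", np), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      samp <- function(col) {
        if (length(col) == mesh$n2) col[cor2]
        else if (length(col) == mesh$n1) col
        else stop("field '", nm, "' has unsupported length ", length(col))
      }
      if (is.matrix(v)) {
        comps <- apply(v, 2, samp)
        writeLines(sprintf("VECTORS %s double", nm), con)
        z3 <- if (ncol(comps) >= 3) comps[, 3] else 0
        writeLines(sprintf("%.10g %.10g %.10g", comps[, 1], comps[, 2], z3), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", samp(v)), con)
      }
    }
  }
  invisible(file)
}
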