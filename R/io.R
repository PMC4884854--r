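#' Export the phantom mesh as legacy ASCII VTK
#'
#' Writes the structured-quadrilateral mesh (optionally deformed by a
#' solved state) as a legacy VTK `UNSTRUCTURED_GRID` text file with the
#' tissue label, material id and — when a state is given — the tangent
#' shear modulus and vertical stress as cell data.  Readable by
#' ParaView and most mesh tools.
#'
#' @param phantom a [build_phantom()] model.
#' @param path output file (conventionally `.vtk`).
#' @param state optional [solve_compression()] state; node coordinates
#'   are then the deformed ones.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(phantom, path, state = NULL) {
  stopifnot(inherits(phantom, "phantom_model"))
  xy <- phantom$node_xy
  if (!is.null(state)) {
    stopifnot(inherits(state, "deformed_state"))
    xy <- xy + state$u
  }
  n <- nrow(xy)
  ne <- nrow(phantom$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "nlswei phantom mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", xy[, 1], xy[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  e <- phantom$elems
  writeLines(sprintf("4 %d %d %d %d", e[, 1], e[, 2], e[, 3], e[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)          # VTK_QUAD
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS tissue_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", phantom$label[phantom$elem_cell]), con)
  if (!is.null(state)) {
    writeLines(c("SCALARS tangent_modulus_pa double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", state$tangent_modulus), con)
    writeLines(c("SCALARS stress_yy_pa double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", state$stress[, 4]), con)
  }
  invisible(path)
}
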