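#' Export a mesh (and optional fields) as legacy ASCII VTK
#'
#' Writes an unstructured grid with the region, transmural-layer and
#' longitudinal-row labels as cell data, optionally a nodal displacement
#' field as point vectors and the per-element mean myofiber/collagen
#' directions as cell vectors, for inspection in ParaView or similar.
#'
#' @param mesh an `lv_mesh`
#' @param path output `.vtk` path
#' @param u optional nodal displacements (length `3 * n_nodes`)
#' @param fibers optional `fiber_field` from [assign_fibers()]
#' @return `path`, invisibly
#' @export
write_mesh_vtk <- function(mesh, path, u = NULL, fibers = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(format(x, digits = 10, trim = TRUE, scientific = FALSE),
                           collapse = " ")
  w("# vtk DataFile Version 3.0")
  w("left-ventricle wall mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", mesh$n_nodes)
  for (i in seq_len(mesh$n_nodes)) w("%s", num(mesh$nodes[i, ]))
  ne <- mesh$n_elems
  w("CELLS %d %d", ne, 9L * ne)
  for (e in seq_len(ne)) w("8 %s", paste(mesh$conn[e, ] - 1L, collapse = " "))
  w("CELL_TYPES %d", ne)
  writeLines(rep("12", ne), con)  # VTK_HEXAHEDRON
  w("CELL_DATA %d", ne)
  w("SCALARS region int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(mesh$elem_region), con)
  w("SCALARS layer int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(mesh$elem_layer), con)
  w("SCALARS long_row int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(mesh$elem_long), con)
  if (!is.null(fibers)) {
    qp_mean <- function(m) {
      out <- matrix(0, ne, 3)
      for (e in seq_len(ne)) {
        v <- colMeans(m[((e - 1L) * 8L + 1L):(e * 8L), , drop = FALSE])
        out[e, ] <- v / sqrt(sum(v^2))
      }
      out
    }
    fm <- qp_mean(fibers$myofiber)
    w("VECTORS myofiber double")
    for (e in seq_len(ne)) w("%s", num(fm[e, ]))
    fc <- qp_mean(fibers$collagen)
    w("VECTORS collagen double")
    for (e in seq_len(ne)) w("%s", num(fc[e, ]))
  }
  if (!is.null(u)) {
    w("POINT_DATA %d", mesh$n_nodes)
    w("VECTORS displacement double")
    um <- matrix(u, ncol = 3, byrow = TRUE)
    for (i in seq_len(mesh$n_nodes)) w("%s", num(um[i, ]))
  }
  invisible(path)
}
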