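# Legacy ASCII VTK export for inspection in ParaView and friends. The
# axisymmetric (r, z) mesh is written as a planar unstructured grid of
# triangles with region/tag cell data; fields are attached as point or cell
# data.

#' Export a mesh (optionally with fields) as a VTK unstructured grid
#'
#' @param mesh A `pnp_mesh`.
#' @param path Output file (conventionally `.vtk`).
#' @param point_data Named list of per-node numeric vectors (e.g. voltage).
#' @param cell_data Named list of per-triangle numeric vectors; per-liquid
#'   triangle vectors (length `length(mesh$liquid)`) are expanded with
#'   zeros on membrane triangles.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric nanopore mesh (r, z)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)  # VTK_TRIANGLE

  cell_data <- c(list(region = as.numeric(mesh$region == "membrane")), cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    if (length(v) == length(mesh$liquid) && length(v) != m) {
      full <- numeric(m); full[mesh$liquid] <- v; v <- full
    }
    stopifnot(length(v) == m)
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", v), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      stopifnot(length(v) == n)
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", v), con)
    }
  }
  invisible(path)
}

#' Export a simulation state as VTK
#'
#' Voltage and per-species concentrations as point data (concentrations are
#' zero on membrane-interior nodes).
#'
#' @param sim A [pnp_simulation()].
#' @param state A `pnp_state`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_state_vtk <- function(sim, state, path) {
  n <- nrow(sim$mesh$nodes)
  pd <- list(voltage = state$V)
  for (s in seq_len(ncol(state$conc))) {
    full <- numeric(n)
    full[sim$mesh$liquid_nodes] <- state$conc[, s]
    pd[[paste0("c_", colnames(state$conc)[s])]] <- full
  }
  write_vtk(sim$mesh, path, point_data = pd)
}
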