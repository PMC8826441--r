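# Minimal legacy ASCII VTK unstructured-grid I/O for hexahedral meshes.
# Covers the subset this package emits: POINTS, CELLS of type 12 (hexahedron),
# and scalar CELL_DATA / POINT_DATA fields.

#' Write a hex mesh (and optional fields) as legacy ASCII VTK
#'
#' @param mesh a [macro_mesh()].
#' @param path output `.vtk` path.
#' @param cell_data named list of per-element numeric vectors.
#' @param point_data named list of per-node numeric vectors.
#' @return the path, invisibly.
#' @export
write_vtk_grid <- function(mesh, path, cell_data = list(), point_data = list()) {
  stopifnot(inherits(mesh, "macro_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  np <- nrow(mesh$nodes)
  ne <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "fglattice unstructured grid",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", np)), con)
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", ne, 9L * ne), con)
  writeLines(apply(mesh$elements - 1L, 1, function(r) paste(c(8L, r), collapse = " ")),
             con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      stopifnot(length(cell_data[[nm]]) == ne)
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 12, trim = TRUE), con)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", np), con)
    for (nm in names(point_data)) {
      stopifnot(length(point_data[[nm]]) == np)
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 12, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK hex grid written by [write_vtk_grid()]
#'
#' @param path a `.vtk` file.
#' @return list with `nodes`, `elements`, and named lists `cell_data`,
#'   `point_data`. Boundary conditions are not part of the format; combine
#'   with supports/loads to build a [macro_mesh()].
#' @export
read_vtk_grid <- function(path) {
  ln <- readLines(path)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  ip <- grep("^POINTS", ln)
  np <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  nodes <- do.call(rbind, lapply(ln[(ip + 1):(ip + np)], num))
  ic <- grep("^CELLS", ln)
  ne <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  cells <- do.call(rbind, lapply(ln[(ic + 1):(ic + ne)], num))
  stopifnot(all(cells[, 1] == 8))
  elements <- matrix(as.integer(cells[, -1]) + 1L, nrow = ne)
  read_fields <- function(start, n) {
    out <- list()
    i <- start
    while (i <= length(ln)) {
      if (grepl("^SCALARS", ln[i])) {
        nm <- strsplit(ln[i], "\\s+")[[1]][2]
        vals <- as.numeric(ln[(i + 2):(i + 1 + n)])
        out[[nm]] <- vals
        i <- i + 2 + n
      } else if (grepl("^(CELL_DATA|POINT_DATA)", ln[i])) {
        break
      } else {
        i <- i + 1
      }
    }
    out
  }
  cd <- grep("^CELL_DATA", ln)
  pd <- grep("^POINT_DATA", ln)
  list(nodes = nodes, elements = elements,
       cell_data = if (length(cd)) read_fields(cd[1] + 1, ne) else list(),
       point_data = if (length(pd)) read_fields(pd[1] + 1, np) else list())
}
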