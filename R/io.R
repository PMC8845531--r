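# Plain-text interchange: legacy-ASCII VTK polydata for meshes, JSON for
# initiation maps, CSV elsewhere.

#' Write a mesh as legacy ASCII VTK polydata
#'
#' Region labels are written as cell data; any per-vertex fields (e.g. IIR)
#' as point data.
#'
#' @param mesh an `la_mesh`.
#' @param path output `.vtk` file.
#' @param point_data named list of per-vertex numeric vectors.
#' @param cell_data named list of per-triangle numeric vectors; the region
#'   label is always included as `region_label`.
#' @return invisibly, the path.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- n_vertices(mesh); m <- n_triangles(mesh)
  writeLines(c("# vtk DataFile Version 3.0",
               "afstress left atrial surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  write(t(mesh$vertices), con, ncolumns = 3)
  writeLines(sprintf("POLYGONS %d %d", m, 4 * m), con)
  write(t(cbind(3L, mesh$triangles - 1L)), con, ncolumns = 4)
  cell_data <- c(list(region_label = as.integer(mesh$region) - 1L),
                 cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    write(cell_data[[nm]], con, ncolumns = 9)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      write(point_data[[nm]], con, ncolumns = 9)
    }
  }
  invisible(path)
}

#' Read back a legacy ASCII VTK polydata file written by [write_vtk()]
#' @param path `.vtk` file
#' @return list with `vertices`, `triangles`, `cell_data`, `point_data`
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  num <- function(lines) as.numeric(unlist(strsplit(trimws(lines), "\\s+")))
  # points span ceiling(n*3/3) lines written 3 per line
  pts <- matrix(num(ln[(ip + 1):(ip + n)]), ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", ln)[1]
  m <- as.integer(strsplit(ln[it], " ")[[1]][2])
  tri <- matrix(num(ln[(it + 1):(it + m)]), ncol = 4, byrow = TRUE)[, 2:4] + 1
  grab <- function(start, count) {
    out <- list()
    i <- start
    while (!is.na(i) && i <= length(ln) && grepl("^SCALARS", ln[i])) {
      nm <- strsplit(ln[i], " ")[[1]][2]
      rows <- ceiling(count / 9)
      out[[nm]] <- num(ln[(i + 2):(i + 1 + rows)])
      i <- i + 2 + rows
    }
    out
  }
  cd <- pd <- list()
  ic <- grep("^CELL_DATA", ln)
  if (length(ic)) cd <- grab(ic[1] + 1, m)
  ipd <- grep("^POINT_DATA", ln)
  if (length(ipd)) pd <- grab(ipd[1] + 1, n)
  list(vertices = pts, triangles = tri, cell_data = cd, point_data = pd)
}

#' Write an initiation map as JSON
#' @param map an `initiation_map`
#' @param path output file
#' @return invisibly, the path
#' @export
write_initiation_map <- function(map, path) {
  jsonlite::write_json(list(variant = map$variant,
                            core_radius = map$core_radius,
                            seeds = map$seeds),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
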