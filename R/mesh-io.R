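## Mesh and field I/O: legacy-ASCII VTK unstructured grids (triangles plus
## tagged boundary line cells) and a plain-text mesh format for golden-file
## tests.  Numbers are written with 17 significant digits so a round trip is
## bit-identical; VTK connectivity is 0-based per the format, the plain-text
## format is 0-based as well.

.tagCodes <- c(LAD_INLET = 1L, GRAFT_INLET = 2L, OUTLET = 3L, WALL = 4L)
.regionCodes <- c(LAD_WALL_PROX = 1L, LAD_WALL_DIST = 2L, GRAFT_WALL = 3L,
                  ANASTOMOSIS = 4L, CHANNEL_WALL = 5L)

.fmt <- function(x) sprintf("%.17g", x)

#' Write a mesh as a legacy-ASCII VTK unstructured grid
#'
#' Triangles are written as VTK cells of type 5 and boundary edges as line
#' cells of type 3; integer cell-data arrays \code{boundary_tag} and
#' \code{wall_region} carry the tags (0 for triangles / untagged).
#'
#' @param mesh a \code{TriMesh}.
#' @param path output file (conventionally .vtk or .vtu).
#' @return Invisibly, \code{path}.
#' @export
writeMeshVTK <- function(mesh, path) {
  n <- nrow(mesh@nodes); m <- nrow(mesh@cells)
  k <- nrow(mesh@boundaryEdges)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "graftflow mesh (2D planar bypass model)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(paste(.fmt(mesh@nodes[, 1]), .fmt(mesh@nodes[, 2]), "0"), con)
  writeLines(sprintf("CELLS %d %d", m + k, 4 * m + 3 * k), con)
  writeLines(paste(3, mesh@cells[, 1] - 1L, mesh@cells[, 2] - 1L,
                   mesh@cells[, 3] - 1L), con)
  writeLines(paste(2, mesh@boundaryEdges[, 1] - 1L,
                   mesh@boundaryEdges[, 2] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m + k), con)
  writeLines(as.character(c(rep(5L, m), rep(3L, k))), con)
  writeLines(c(sprintf("CELL_DATA %d", m + k),
               "SCALARS boundary_tag int 1", "LOOKUP_TABLE default"), con)
  tagC <- unname(.tagCodes[mesh@boundaryTag])
  writeLines(as.character(c(rep(0L, m), tagC)), con)
  writeLines(c("SCALARS wall_region int 1", "LOOKUP_TABLE default"), con)
  regC <- ifelse(is.na(mesh@wallRegion), 0L,
                 unname(.regionCodes[mesh@wallRegion]))
  writeLines(as.character(c(rep(0L, m), regC)), con)
  invisible(path)
}

#' Read a mesh written by \code{\link{writeMeshVTK}}
#' @param path VTK file path.
#' @return A \code{TriMesh} (meta only records the source file).
#' @export
readMeshVTK <- function(path) {
  lines <- readLines(path)
  ptHdr <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ptHdr], " +")[[1]][2])
  pts <- utils::read.table(text = lines[(ptHdr + 1):(ptHdr + n)])
  cellHdr <- grep("^CELLS", lines)[1]
  ncell <- as.integer(strsplit(lines[cellHdr], " +")[[1]][2])
  rows <- strsplit(trimws(lines[(cellHdr + 1):(cellHdr + ncell)]), " +")
  sizes <- vapply(rows, function(r) as.integer(r[1]), 0L)
  tris <- t(vapply(rows[sizes == 3], function(r) as.integer(r[2:4]), integer(3)))
  segs <- t(vapply(rows[sizes == 2], function(r) as.integer(r[2:3]), integer(2)))
  tagHdr <- grep("^SCALARS boundary_tag", lines)[1]
  vals <- as.integer(unlist(strsplit(trimws(
    lines[(tagHdr + 2):(tagHdr + 1 + ncell)]), " +")))
  tagC <- vals[sizes == 2]
  regHdr <- grep("^SCALARS wall_region", lines)[1]
  rvals <- as.integer(unlist(strsplit(trimws(
    lines[(regHdr + 2):(regHdr + 1 + ncell)]), " +")))
  regC <- rvals[sizes == 2]
  tagNames <- names(.tagCodes)[tagC]
  regNames <- c(NA_character_, names(.regionCodes))[regC + 1L]
  nodes <- as.matrix(pts[, 1:2])
  dimnames(nodes) <- NULL
  new("TriMesh", nodes = nodes,
      cells = tris + 1L, boundaryEdges = segs + 1L,
      boundaryTag = tagNames, wallRegion = regNames,
      meta = list(kind = "imported", source = path))
}

#' Write a mesh in the plain-text golden-file format
#'
#' Sections: a version line, \code{nodes} (x y in meters), \code{cells}
#' (0-based node triples) and \code{boundary} (0-based node pairs with tag
#' and region strings; \code{-} for no region).
#'
#' @param mesh a \code{TriMesh}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeMeshTxt <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graftflow-mesh 1", con)
  writeLines(sprintf("nodes %d", nrow(mesh@nodes)), con)
  writeLines(paste(.fmt(mesh@nodes[, 1]), .fmt(mesh@nodes[, 2])), con)
  writeLines(sprintf("cells %d", nrow(mesh@cells)), con)
  writeLines(paste(mesh@cells[, 1] - 1L, mesh@cells[, 2] - 1L,
                   mesh@cells[, 3] - 1L), con)
  writeLines(sprintf("boundary %d", nrow(mesh@boundaryEdges)), con)
  writeLines(paste(mesh@boundaryEdges[, 1] - 1L, mesh@boundaryEdges[, 2] - 1L,
                   mesh@boundaryTag,
                   ifelse(is.na(mesh@wallRegion), "-", mesh@wallRegion)), con)
  invisible(path)
}

#' Read a plain-text mesh
#' @param path file written by \code{\link{writeMeshTxt}}.
#' @return A \code{TriMesh}.
#' @export
readMeshTxt <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "graftflow-mesh"))
    stop("not a graftflow plain-text mesh")
  i <- 2
  stopifnot(startsWith(lines[i], "nodes"))
  n <- as.integer(strsplit(lines[i], " ")[[1]][2])
  nodes <- as.matrix(utils::read.table(text = lines[(i + 1):(i + n)]))
  i <- i + n + 1
  stopifnot(startsWith(lines[i], "cells"))
  m <- as.integer(strsplit(lines[i], " ")[[1]][2])
  cells <- as.matrix(utils::read.table(text = lines[(i + 1):(i + m)])) + 1L
  i <- i + m + 1
  stopifnot(startsWith(lines[i], "boundary"))
  k <- as.integer(strsplit(lines[i], " ")[[1]][2])
  bt <- utils::read.table(text = lines[(i + 1):(i + k)],
                          colClasses = c("integer", "integer", "character",
                                         "character"))
  dimnames(nodes) <- NULL; dimnames(cells) <- NULL
  be <- as.matrix(bt[, 1:2]) + 1L
  dimnames(be) <- NULL
  new("TriMesh", nodes = nodes, cells = cells, boundaryEdges = be,
      boundaryTag = bt[, 3],
      wallRegion = ifelse(bt[, 4] == "-", NA_character_, bt[, 4]),
      meta = list(kind = "imported", source = path))
}

#' Export flow snapshots as a VTK time series
#'
#' Writes one legacy-ASCII VTK unstructured-grid file per stored snapshot
#' (point data: velocity vectors in m/s, pressure in Pa) plus a plain-text
#' series index with the snapshot times.
#'
#' @param sol a \code{FlowSolution}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the index file path.
#' @export
exportFieldsVTK <- function(sol, dir, prefix = "flow") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mesh <- sol@mesh
  n <- nrow(mesh@nodes); m <- nrow(mesh@cells)
  files <- character(length(sol@times))
  for (j in seq_along(sol@times)) {
    f <- sprintf("%s_%04d.vtk", prefix, j - 1L)
    con <- file(file.path(dir, f), "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("graftflow fields t=%s s", .fmt(sol@times[j])),
                 "ASCII", "DATASET UNSTRUCTURED_GRID",
                 sprintf("POINTS %d double", n)), con)
    writeLines(paste(.fmt(mesh@nodes[, 1]), .fmt(mesh@nodes[, 2]), "0"), con)
    writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
    writeLines(paste(3, mesh@cells[, 1] - 1L, mesh@cells[, 2] - 1L,
                     mesh@cells[, 3] - 1L), con)
    writeLines(sprintf("CELL_TYPES %d", m), con)
    writeLines(as.character(rep(5L, m)), con)
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "VECTORS velocity double"), con)
    writeLines(paste(.fmt(sol@u[, j]), .fmt(sol@v[, j]), "0"), con)
    writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(.fmt(sol@p[, j]), con)
    close(con)
    files[j] <- f
  }
  idx <- file.path(dir, sprintf("%s.series.txt", prefix))
  writeLines(c("# graftflow VTK series: file time_s",
               paste(files, .fmt(sol@times))), idx)
  invisible(idx)
}

#' Read point data back from an exported field file
#' @param path a VTK file written by \code{\link{exportFieldsVTK}}.
#' @return list(points, u, v, p).
#' @export
readFieldsVTK <- function(path) {
  lines <- readLines(path)
  ptHdr <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ptHdr], " +")[[1]][2])
  pts <- as.matrix(utils::read.table(text = lines[(ptHdr + 1):(ptHdr + n)]))
  vHdr <- grep("^VECTORS velocity", lines)[1]
  vel <- as.matrix(utils::read.table(text = lines[(vHdr + 1):(vHdr + n)]))
  pHdr <- grep("^SCALARS pressure", lines)[1]
  p <- as.numeric(lines[(pHdr + 2):(pHdr + 1 + n)])
  list(points = pts[, 1:2], u = vel[, 1], v = vel[, 2], p = p)
}
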