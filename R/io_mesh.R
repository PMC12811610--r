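## Mesh and table export: ASCII PLY, legacy VTK unstructured grid,
## FreeSurfer binary surface/overlay formats, delimited tables.

#' Write / read a triangle surface as ASCII PLY
#'
#' Optional per-vertex scalar columns are written as extra float properties
#' and restored on reading.
#'
#' @param s a [TriangleSurface-class].
#' @param path output path.
#' @param scalars named list of per-vertex numeric vectors.
#' @return `path` (write) or a [TriangleSurface-class] (read).
#' @export
writeSurfacePLY <- function(s, path, scalars = NULL) {
  nv <- nrow(s@vertices); nf <- nrow(s@triangles)
  con <- file(path, "wb")
  on.exit(close(con))
  props <- c("x", "y", "z", names(scalars))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           sprintf("property float %s", props),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  V <- s@vertices
  for (nm in names(scalars)) V <- cbind(V, scalars[[nm]])
  writeLines(do.call(paste, lapply(seq_len(ncol(V)), function(c0)
    sprintf("%.17g", V[, c0]))), con)
  writeLines(paste(3, s@triangles[, 1] - 1L, s@triangles[, 2] - 1L,
                   s@triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname writeSurfacePLY
#' @export
readSurfacePLY <- function(path) {
  lines <- readLines(path)
  endH <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  props <- sub("property float ", "",
               grep("^property float", lines, value = TRUE))
  vdat <- utils::read.table(text = lines[endH + seq_len(nv)],
                            col.names = props)
  fdat <- utils::read.table(text = lines[endH + nv + seq_len(nf)])
  tris <- unname(as.matrix(fdat[, 2:4])) + 1L
  storage.mode(tris) <- "integer"
  vd <- data.frame(subfield = rep(NA_integer_, nv), cap = NA_character_)
  extra <- setdiff(props, c("x", "y", "z"))
  for (nm in extra) vd[[nm]] <- vdat[[nm]]
  verts <- unname(as.matrix(vdat[, c("x", "y", "z")]))
  new("TriangleSurface", vertices = verts, triangles = tris, vertexData = vd)
}

#' Write a tetrahedral mesh as legacy VTK unstructured grid
#'
#' @param mesh a [TetrahedralMesh-class].
#' @param path output path (.vtk).
#' @param scalars named list of per-vertex numeric vectors (POINT_DATA).
#' @return `path`, invisibly.
#' @export
writeTetVTK <- function(mesh, path, scalars = NULL) {
  nv <- nrow(mesh@vertices); nt <- nrow(mesh@tets)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "hipposheet tetrahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nv)), con)
  writeLines(do.call(paste, lapply(1:3, function(c0)
    sprintf("%.17g", mesh@vertices[, c0]))), con)
  writeLines(sprintf("CELLS %d %d", nt, 5L * nt), con)
  writeLines(paste(4, mesh@tets[, 1] - 1L, mesh@tets[, 2] - 1L,
                   mesh@tets[, 3] - 1L, mesh@tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(as.character(rep(10L, nt)), con)
  if (length(scalars)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", scalars[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write a surface in FreeSurfer binary format (with overlay support)
#'
#' `writeSurfaceFS` writes the classic big-endian triangle surface format;
#' `writeCurvFS` writes a per-vertex overlay in the "new" curv format.
#'
#' @param s a [TriangleSurface-class].
#' @param path output path.
#' @param values per-vertex numeric vector (overlay).
#' @param nFaces face count stored in the overlay header.
#' @return `path`, invisibly.
#' @export
writeSurfaceFS <- function(s, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xfe)), con)
  writeLines(c("created by hipposheet", ""), con)   # two newline-terminated
  writeBin(as.integer(c(nrow(s@vertices), nrow(s@triangles))), con,
           size = 4, endian = "big")
  writeBin(as.numeric(t(s@vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(s@triangles) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

#' @rdname writeSurfaceFS
#' @export
writeCurvFS <- function(values, path, nFaces = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xff)), con)
  writeBin(as.integer(c(length(values), nFaces, 1L)), con, size = 4,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

#' Write the thickness grid as a delimited table
#'
#' Columns: i, j, u_ml, u_ap, x, y, z, thickness, curvature, flag. The
#' format is fixed-precision, so identical grids serialize byte-identically.
#'
#' @param grid a [ThicknessGrid-class].
#' @param path output path (.csv).
#' @return `path`, invisibly.
#' @export
writeGridTable <- function(grid, path) {
  N <- grid@N; M <- grid@M
  k <- seq_len(N * M)
  df <- data.frame(
    i = ((k - 1L) %% N) + 1L, j = ((k - 1L) %/% N) + 1L,
    u_ml = grid@uml[((k - 1L) %% N) + 1L],
    u_ap = grid@uap[((k - 1L) %/% N) + 1L],
    x = grid@points[, 1], y = grid@points[, 2], z = grid@points[, 3],
    thickness = as.numeric(grid@thickness),
    curvature = as.numeric(grid@curvature),
    flag = as.integer(grid@flags))
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.8f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGridTable
#' @export
readGridTable <- function(path) {
  df <- utils::read.csv(path)
  N <- max(df$i); M <- max(df$j)
  new("ThicknessGrid", N = N, M = M,
      uml = (seq_len(N) - 0.5) / N, uap = (seq_len(M) - 0.5) / M,
      points = as.matrix(df[, c("x", "y", "z")]),
      uie = rep(0.5, N * M),
      thickness = matrix(df$thickness, N, M),
      curvature = matrix(df$curvature, N, M),
      flags = matrix(as.integer(df$flag), N, M))
}

## fixed-precision CSV writer for generic per-vertex tables
writeVertexTable <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.8f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
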