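## Reference geometries with closed-form solutions: used as independent
## oracles (Neumann modes, harmonic annulus, cylinder/sphere curvature) and
## exported because they are handy for operator validation.

#' Reference meshes with closed-form solutions
#'
#' Simple structured meshes used to validate the discrete operators:
#' a flat rectangle strip (Neumann eigenfunctions `cos(pi k x / L)`), a box
#' tetrahedral mesh (linear harmonic coordinates), a cylindrical-annulus
#' sector (harmonic field `ln(r/r0)/ln(r1/r0)` between the walls), a tube
#' and a sphere surface (constant mean curvature 1/(2r) and 1/r).
#'
#' @param L,W rectangle extents (mm); `nx`, `ny` cells per side.
#' @return `makeRectangleSurface`: a [TriangleSurface-class] in the z = 0
#'   plane.
#' @name referenceGeometries
#' @export
makeRectangleSurface <- function(L = 2, W = 1, nx = 40L, ny = 20L) {
  xs <- seq(0, L, length.out = nx + 1L)
  ys <- seq(0, W, length.out = ny + 1L)
  verts <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L), 0)
  vid <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  tris <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  new("TriangleSurface", vertices = verts, triangles = tris,
      vertexData = data.frame(subfield = rep(NA_integer_, nrow(verts)),
                              cap = NA_character_))
}

## Kuhn-subdivide a structured node grid given as an (n1 x n2 x n3) x 3
## coordinate array; returns a TetrahedralMesh.
structuredTetMesh <- function(coords, n) {
  corner <- list()
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    corner[[1 + dx + 2 * dy + 4 * dz]] <- dx + dy * n[1] + dz * n[1] * n[2]
  nc <- n - 1L
  cpos <- arrayInd(seq_len(prod(nc)), nc)
  base <- cpos[, 1] + (cpos[, 2] - 1) * n[1] + (cpos[, 3] - 1) * n[1] * n[2]
  tets <- do.call(rbind, lapply(1:6, function(t)
    cbind(base + corner[[.kuhnTets[t, 1]]], base + corner[[.kuhnTets[t, 2]]],
          base + corner[[.kuhnTets[t, 3]]], base + corner[[.kuhnTets[t, 4]]])))
  vol <- tetVolumes(NULL, coords, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
                 tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  fg <- faceGroups(faces)
  btris <- faces[fg$count == 1L, , drop = FALSE]
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])[fg$count == 1L]
  nrm <- triangleNormals(coords, btris)
  dvec <- coords[opp, , drop = FALSE] - coords[btris[, 1], , drop = FALSE]
  inward <- rowSums(nrm * dvec) > 0
  if (any(inward)) btris[inward, c(2, 3)] <- btris[inward, c(3, 2)]
  new("TetrahedralMesh", vertices = coords, tets = tets,
      boundaryTriangles = btris,
      vertexData = data.frame(subfield = rep(NA_integer_, nrow(coords)),
                              cap = NA_character_))
}

#' @rdname referenceGeometries
#' @param a,b,cc box extents (mm); `n1`,`n2`,`n3` cells per side.
#' @export
makeBoxTetMesh <- function(a = 1, b = 1, cc = 1, n1 = 6L, n2 = 6L, n3 = 6L) {
  n <- c(n1, n2, n3) + 1L
  xs <- seq(0, a, length.out = n[1])
  ys <- seq(0, b, length.out = n[2])
  zs <- seq(0, cc, length.out = n[3])
  coords <- cbind(rep(xs, times = n[2] * n[3]),
                  rep(rep(ys, each = n[1]), times = n[3]),
                  rep(zs, each = n[1] * n[2]))
  structuredTetMesh(coords, n)
}

#' @rdname referenceGeometries
#' @param r0,r1 inner and outer wall radius (mm); `h` height; `phi` angular
#'   span of the sector (radians); `nr`,`nphi`,`nz` cells per direction.
#' @export
makeAnnulusTetMesh <- function(r0 = 5, r1 = 10, h = 4, phi = pi / 2,
                               nr = 10L, nphi = 24L, nz = 4L) {
  n <- c(nr, nphi, nz) + 1L
  rs <- seq(r0, r1, length.out = n[1])
  ps <- seq(0, phi, length.out = n[2])
  zs <- seq(0, h, length.out = n[3])
  coords <- cbind(rep(rs, times = n[2] * n[3]) *
                    cos(rep(rep(ps, each = n[1]), times = n[3])),
                  rep(rs, times = n[2] * n[3]) *
                    sin(rep(rep(ps, each = n[1]), times = n[3])),
                  rep(zs, each = n[1] * n[2]))
  mesh <- structuredTetMesh(coords, n)
  attr(mesh, "wallVertices") <- list(
    inner = which(abs(sqrt(coords[, 1]^2 + coords[, 2]^2) - r0) < 1e-9),
    outer = which(abs(sqrt(coords[, 1]^2 + coords[, 2]^2) - r1) < 1e-9))
  mesh
}

#' @rdname referenceGeometries
#' @param r tube/sphere radius (mm); `hh` tube height; `ntheta`,`nzz`
#'   angular/axial resolution.
#' @export
makeTubeSurface <- function(r = 5, hh = 20, ntheta = 60L, nzz = 30L) {
  th <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  zs <- seq(0, hh, length.out = nzz + 1L)
  verts <- cbind(r * cos(rep(th, times = nzz + 1L)),
                 r * sin(rep(th, times = nzz + 1L)),
                 rep(zs, each = ntheta))
  vid <- function(i, j) (j - 1L) * ntheta + (i - 1L) %% ntheta + 1L
  i <- rep(seq_len(ntheta), times = nzz)
  j <- rep(seq_len(nzz), each = ntheta)
  tris <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  new("TriangleSurface", vertices = verts, triangles = tris,
      vertexData = data.frame(subfield = rep(NA_integer_, nrow(verts)),
                              cap = NA_character_))
}

#' @rdname referenceGeometries
#' @export
makeSphereSurface <- function(r = 5, ntheta = 48L, nphi = 24L) {
  ## latitude rings (excluding poles) + two pole vertices
  ph <- seq(0, pi, length.out = nphi + 1L)[-c(1L, nphi + 1L)]
  th <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  ring <- function(p) cbind(r * sin(p) * cos(th), r * sin(p) * sin(th),
                            r * cos(p))
  verts <- do.call(rbind, lapply(ph, ring))
  north <- nrow(verts) + 1L; south <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, r), c(0, 0, -r))
  vid <- function(i, j) (j - 1L) * ntheta + (i - 1L) %% ntheta + 1L
  i <- rep(seq_len(ntheta), times = length(ph) - 1L)
  j <- rep(seq_len(length(ph) - 1L), each = ntheta)
  tris <- rbind(cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i + 1L, j)),
                cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j + 1L)))
  i <- seq_len(ntheta)
  tris <- rbind(tris,
                cbind(rep(north, ntheta), vid(i, 1L), vid(i + 1L, 1L)),
                cbind(rep(south, ntheta), vid(i + 1L, length(ph)),
                      vid(i, length(ph))))
  new("TriangleSurface", vertices = verts, triangles = tris,
      vertexData = data.frame(subfield = rep(NA_integer_, nrow(verts)),
                              cap = NA_character_))
}
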