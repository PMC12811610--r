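## meshing: from the binary body mask to a smoothed closed triangle surface
## with a conforming tetrahedral volume mesh, plus label transfer.
##
## The volume mesh is generated directly from the voxel lattice: the
## smoothed indicator function is sampled at voxel centers, every lattice
## cell is subdivided into six tetrahedra (Freudenthal/Kuhn scheme, which is
## conforming across cells), and each tetrahedron is clipped against the 0.5
## iso-level of the implicit function (marching tetrahedra with a
## min-vertex-index diagonal rule, so neighboring cells triangulate shared
## cut quads identically). The boundary of the clipped complex is the
## extracted surface, so surface and volume mesh conform by construction.
## The anterior/posterior cut planes are kept planar: the implicit function
## is extended beyond the body by slice replication and the lattice is
## truncated at the cap slice planes.

## slot index of the unordered vertex pair (i, j) within a tet (1..6)
.edgeSlot <- matrix(c(0, 1, 2, 3,
                      1, 0, 4, 5,
                      2, 4, 0, 6,
                      3, 5, 6, 0), 4, 4)

.tetEdgePairs <- rbind(c(1, 2), c(1, 3), c(1, 4),
                       c(2, 3), c(2, 4), c(3, 4))

## Split the cyclic quad (A,B,C,D) into two triangles through the diagonal
## that emanates from the globally smallest vertex index. Both tets sharing
## the quad apply the same rule, so the triangulation conforms.
splitQuad <- function(A, B, C, D) {
  if (min(A, C) < min(B, D)) rbind(c(A, B, C), c(A, C, D))
  else rbind(c(B, C, D), c(B, D, A))
}

## Clip one tetrahedron against the iso-level: keep the positive side.
## ids: 4 global vertex ids; pos: logical(4); cuts: global ids of the edge
## cut points in .tetEdgePairs slot order (NA where the edge has no cut).
## Returns a matrix of sub-tets (rows of 4 global ids), unoriented.
clipTetTopo <- function(ids, pos, cuts) {
  np <- sum(pos)
  cut <- function(i, j) cuts[.edgeSlot[i, j]]
  if (np == 4L) return(matrix(ids, 1, 4))
  if (np == 0L) return(NULL)
  P <- which(pos); N <- which(!pos)
  if (np == 1L) {
    p <- P[1]
    return(matrix(c(ids[p], cut(p, N[1]), cut(p, N[2]), cut(p, N[3])), 1, 4))
  }
  if (np == 3L) {
    p1 <- ids[P[1]]; p2 <- ids[P[2]]; p3 <- ids[P[3]]
    q1 <- cut(P[1], N[1]); q2 <- cut(P[2], N[1]); q3 <- cut(P[3], N[1])
    tris <- rbind(c(q1, q2, q3),
                  splitQuad(p1, p2, q2, q1),
                  splitQuad(p2, p3, q3, q2),
                  splitQuad(p3, p1, q1, q3))
    apex <- p1
  } else {
    p1 <- ids[P[1]]; p2 <- ids[P[2]]
    q11 <- cut(P[1], N[1]); q12 <- cut(P[1], N[2])
    q21 <- cut(P[2], N[1]); q22 <- cut(P[2], N[2])
    tris <- rbind(splitQuad(p1, p2, q21, q11),
                  splitQuad(p1, p2, q22, q12),
                  c(p2, q21, q22),
                  splitQuad(q11, q21, q22, q12))
    apex <- p1
  }
  keep <- tris[, 1] != apex & tris[, 2] != apex & tris[, 3] != apex
  tris <- tris[keep, , drop = FALSE]
  cbind(apex, tris, deparse.level = 0)
}

## The six Kuhn tetrahedra of a unit cell, as indices into the 8 cell
## corners ordered by idx = 1 + dx + 2*dy + 4*dz.
.kuhnTets <- local({
  cidx <- function(v) as.integer(1 + v[1] + 2 * v[2] + 4 * v[3])
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  t(vapply(perms, function(p) {
    e <- diag(3)
    c(cidx(c(0, 0, 0)), cidx(e[p[1], ]), cidx(e[p[1], ] + e[p[2], ]),
      cidx(c(1, 1, 1)))
  }, integer(4)))
})

#' Build the conforming tetrahedral mesh of the hippocampal body
#'
#' Samples a Gaussian-smoothed implicit function of the body mask at the
#' voxel centers, subdivides every lattice cell into six tetrahedra, clips
#' them against the 0.5 iso-level, and relaxes vertex positions by a mild,
#' movement-capped Laplacian smoothing (boundary vertices along the surface
#' graph, interior vertices along the volume graph; the anterior/posterior
#' cap cross-sections stay planar and tet orientations stay positive).
#'
#' @param m a [BodyMask-class] that passed [checkMaskTopology()].
#' @param smoothingIterations vertex relaxation iterations (default 10);
#'   a vertex never moves by more than one voxel diagonal in total.
#' @param implicitSigma standard deviation (voxels, per axis) of the Gaussian applied to
#'   the binary mask before iso-extraction.
#' @param lambda relaxation factor per iteration.
#' @return a [TetrahedralMesh-class] with cap tags in `vertexData`.
#' @export
buildBodyTetMesh <- function(m, smoothingIterations = 10L,
                             implicitSigma = 1, lambda = 0.5) {
  mask <- m@mask
  n <- dim(mask)
  ap <- m@apAxis
  lo <- m@apRange[1]; hi <- m@apRange[2]
  voxdim <- voxelSizes(m@affine)
  if (hi - lo < 2L)
    hsError("meshing", "body spans fewer than 3 slices along the anterior/posterior axis")

  ## implicit function: replicate the body end slices outward so the mesh
  ## is cut flat at the cap planes, then smooth
  rep_idx <- pmin(pmax(seq_len(n[ap]), lo), hi)
  ext <- switch(ap, mask[rep_idx, , ], mask[, rep_idx, ], mask[, , rep_idx])
  dim(ext) <- n
  ## smooth the indicator; back off towards the raw binary field if
  ## thresholding the smoothed field would erode thin structures (changed
  ## foreground component count)
  nComp <- arrayComponents(ext, 6L)$n
  sigma <- implicitSigma
  repeat {
    phi <- if (sigma > 0) gaussianSmooth3D(ext * 1.0, rep_len(sigma, 3))
      else ext * 1.0
    if (arrayComponents(phi > 0.5, 6L)$n == nComp || sigma == 0) break
    sigma <- if (sigma > implicitSigma / 4) sigma / 2 else 0
  }
  s <- phi - 0.5
  s[abs(s) < 1e-4] <- 1e-4

  ## lattice cells (between voxel centers), truncated at the cap planes
  nc <- n - 1L
  pos <- s > 0
  sub <- function(a, d) a[(1:nc[1]) + d[1], (1:nc[2]) + d[2],
                          (1:nc[3]) + d[3], drop = FALSE]
  corner <- list()
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    corner[[1 + dx + 2 * dy + 4 * dz]] <- c(dx, dy, dz)
  cnt <- array(0L, nc)
  for (d in corner) cnt <- cnt + sub(pos, d)
  apIdx <- slice1d(nc, ap, seq_len(nc[ap]) >= lo & seq_len(nc[ap]) <= hi - 1L)
  active <- which(cnt > 0L & apIdx)
  if (!length(active))
    hsError("meshing", "no foreground cells: empty implicit region")
  cpos <- arrayInd(active, nc)
  base <- as.numeric(cpos[, 1] + (cpos[, 2] - 1) * n[1] +
                       (cpos[, 3] - 1) * n[1] * n[2])
  off8 <- vapply(corner, function(d) d[1] + d[2] * n[1] + d[3] * n[1] * n[2],
                 numeric(1))

  ## expand to tets (6 per cell); classify
  cellFull <- cnt[active] == 8L
  fullTets <- NULL
  if (any(cellFull)) {
    b <- base[cellFull]
    fullTets <- do.call(rbind, lapply(1:6, function(t)
      cbind(b + off8[.kuhnTets[t, 1]], b + off8[.kuhnTets[t, 2]],
            b + off8[.kuhnTets[t, 3]], b + off8[.kuhnTets[t, 4]])))
  }
  clipped <- NULL
  nNode <- prod(n)
  cutTable <- NULL
  if (any(!cellFull)) {
    b <- base[!cellFull]
    mt <- do.call(rbind, lapply(1:6, function(t)
      cbind(b + off8[.kuhnTets[t, 1]], b + off8[.kuhnTets[t, 2]],
            b + off8[.kuhnTets[t, 3]], b + off8[.kuhnTets[t, 4]])))
    sv <- matrix(s[mt], ncol = 4)
    npos <- rowSums(sv > 0)
    if (any(npos == 4L)) fullTets <- rbind(fullTets,
                                           mt[npos == 4L, , drop = FALSE])
    mix <- npos > 0L & npos < 4L
    mt <- mt[mix, , drop = FALSE]; sv <- sv[mix, , drop = FALSE]
    if (nrow(mt)) {
      ## global cut-point table over all sign-change edges
      keyAll <- tAll <- loAll <- hiAll <- NULL
      slotKeys <- matrix(NA_real_, nrow(mt), 6)
      for (sl in 1:6) {
        i <- .tetEdgePairs[sl, 1]; j <- .tetEdgePairs[sl, 2]
        chg <- (sv[, i] > 0) != (sv[, j] > 0)
        a <- mt[chg, i]; bb <- mt[chg, j]
        k <- pairKey(a, bb)
        slotKeys[chg, sl] <- k
        keyAll <- c(keyAll, k)
      }
      uk <- unique(keyAll)
      loN <- floor(uk / 2^26); hiN <- uk - loN * 2^26
      tCut <- s[loN] / (s[loN] - s[hiN])
      tCut <- pmin(pmax(tCut, 0.02), 0.98)
      cutTable <- list(lo = loN, hi = hiN, t = tCut)
      cutIds <- matrix(NA_real_, nrow(mt), 6)
      for (sl in 1:6) {
        hit <- !is.na(slotKeys[, sl])
        cutIds[hit, sl] <- nNode + match(slotKeys[hit, sl], uk)
      }
      out <- vector("list", nrow(mt))
      for (r in seq_len(nrow(mt)))
        out[[r]] <- clipTetTopo(mt[r, ], sv[r, ] > 0, cutIds[r, ])
      clipped <- do.call(rbind, out)
    }
  }
  allTets <- rbind(fullTets, clipped)

  ## compact vertex ids and compute coordinates
  present <- sort(unique(as.vector(allTets)))
  tets <- matrix(match(as.vector(allTets), present), ncol = 4)
  isNode <- present <= nNode
  idxco <- matrix(0, length(present), 3)
  idxco[isNode, ] <- arrayInd(present[isNode], n)
  if (any(!isNode)) {
    ci <- present[!isNode] - nNode
    iLo <- arrayInd(cutTable$lo[ci], n)
    iHi <- arrayInd(cutTable$hi[ci], n)
    tt <- cutTable$t[ci]
    idxco[!isNode, ] <- iLo * (1 - tt) + iHi * tt
  }
  ## stretch the anterior/posterior coordinate so that cut planes coincide
  ## with the outer faces of the end slices (node layers sit at voxel
  ## centers, half a voxel inside the mask extent); ends where the mask
  ## does not reach the slice limit are not cut and not stretched
  occ <- apply(mask, ap, any)
  hasLow <- occ[lo]; hasHigh <- occ[hi]
  span <- hi - lo
  idxco[, ap] <- (idxco[, ap] - lo) *
    (span + 0.5 * (hasLow + hasHigh)) / span + lo - 0.5 * hasLow
  verts <- indexToWorld(m@affine, idxco)

  ## orient positively, drop degenerate slivers
  vol <- tetVolumes(NULL, verts, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  keep <- abs(vol) > 1e-10
  tets <- tets[keep, , drop = FALSE]

  ## boundary faces (occurring once), oriented outward
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
                 tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  fg <- faceGroups(faces)
  bidx <- which(fg$count == 1L)
  btris <- faces[bidx, , drop = FALSE]
  bopp <- opp[bidx]
  nrm <- triangleNormals(verts, btris)
  dvec <- verts[bopp, , drop = FALSE] - verts[btris[, 1], , drop = FALSE]
  inward <- rowSums(nrm * dvec) > 0
  if (any(inward)) btris[inward, c(2, 3)] <- btris[inward, c(3, 2)]

  ## topology guards (the pipeline refuses defective geometry)
  ec <- edgeCounts(btris)
  if (any(ec$counts != 2L))
    hsError("meshing", "extracted surface is not a closed manifold (%d defective edges)",
            sum(ec$counts != 2L))
  if (max(triangleComponents(btris)) != 1L)
    hsError("meshing", "extracted surface has multiple components")
  chi <- surfaceEulerCharacteristic(NULL, btris)
  if (chi != 2L)
    hsError("meshing", "extracted surface has genus > 0 (Euler characteristic %d)", chi)

  ## cap tags from the lattice index coordinates
  apco <- idxco[, ap]
  capLow <- hasLow & abs(apco - (lo - 0.5)) < 1e-9
  capHigh <- hasHigh & abs(apco - (hi + 0.5)) < 1e-9
  cap <- rep(NA_character_, nrow(verts))
  if (m@anteriorEnd == 2L) {
    cap[capHigh] <- "anterior"; cap[capLow] <- "posterior"
  } else {
    cap[capLow] <- "anterior"; cap[capHigh] <- "posterior"
  }

  verts <- smoothTetMeshVertices(verts, tets, btris, capLow | capHigh,
                                 idxco, ap, m@affine,
                                 iterations = smoothingIterations,
                                 lambda = lambda,
                                 maxMove = sqrt(sum(voxdim^2)))

  new("TetrahedralMesh", vertices = verts, tets = tets,
      boundaryTriangles = btris,
      vertexData = data.frame(subfield = rep(NA_integer_, nrow(verts)),
                              cap = cap, stringsAsFactors = FALSE))
}

## Movement-capped Laplacian relaxation of the mesh vertices. Surface
## vertices average over the surface graph, interior ones over the tet edge
## graph; cap vertices are re-projected onto their lattice plane; global
## damping preserves positive tet volumes.
smoothTetMeshVertices <- function(verts, tets, btris, isCap, idxco, ap,
                                  affine, iterations, lambda, maxMove) {
  if (iterations < 1L) return(verts)
  nv <- nrow(verts)
  surfV <- unique(as.vector(btris))
  isSurf <- rep(FALSE, nv); isSurf[surfV] <- TRUE
  surfAdj <- adjacencyFromEdges(surfaceEdges(btris), nv)
  tetE <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  tetE <- tetE[!duplicated(pairKey(tetE[, 1], tetE[, 2])), , drop = FALSE]
  volAdj <- adjacencyFromEdges(tetE, nv)
  P0 <- verts; P <- verts
  capPlane <- idxco[, ap]
  projectCaps <- function(P) {
    if (!any(isCap)) return(P)
    idx <- worldToIndex(affine, P[isCap, , drop = FALSE])
    idx[, ap] <- capPlane[isCap]
    P[isCap, ] <- indexToWorld(affine, idx)
    P
  }
  ## Taubin-style shrink/inflate pair keeps the relaxation volume-conserving
  mu <- -1.04 * lambda
  for (it in seq_len(iterations)) {
    for (fac in c(lambda, mu)) {
      tgt <- neighborMeans(surfAdj, P)
      P[isSurf, ] <- P[isSurf, ] + fac * (tgt[isSurf, ] - P[isSurf, ])
      P <- projectCaps(P)
    }
    tgtV <- neighborMeans(volAdj, P)
    ii <- !isSurf
    P[ii, ] <- P[ii, ] + 0.5 * lambda * (tgtV[ii, ] - P[ii, ])
    d <- P - P0
    len <- sqrt(rowSums(d^2))
    f <- ifelse(len > maxMove, maxMove / pmax(len, 1e-12), 1)
    P <- P0 + d * f
  }
  ## damp globally if any tet inverted
  for (k in 0:20) {
    if (min(tetVolumes(NULL, P, tets)) > 1e-12) break
    P <- P0 + (P - P0) * 0.5
    if (k == 20L) P <- P0
  }
  P
}

#' Extract the smoothed closed body surface
#'
#' Convenience wrapper around [buildBodyTetMesh()] that returns the boundary
#' [TriangleSurface-class] (closed, oriented, manifold, genus 0). The
#' conforming volume mesh is attached as attribute `volumeMesh` and reused
#' by [tetrahedralize()], so surface and volume vertices coincide exactly.
#'
#' @inheritParams buildBodyTetMesh
#' @return a [TriangleSurface-class] with cap tags and a `tetVertex` column
#'   mapping surface vertices to volume-mesh vertices.
#' @export
extractSmoothSurface <- function(m, smoothingIterations = 10L,
                                 implicitSigma = 1, lambda = 0.5) {
  mesh <- buildBodyTetMesh(m, smoothingIterations, implicitSigma, lambda)
  surf <- surfaceFromMesh(mesh)
  attr(surf, "volumeMesh") <- mesh
  surf
}

## Boundary surface of a tet mesh as a stand-alone TriangleSurface.
surfaceFromMesh <- function(mesh) {
  sv <- sort(unique(as.vector(mesh@boundaryTriangles)))
  remap <- integer(nrow(mesh@vertices))
  remap[sv] <- seq_along(sv)
  tris <- matrix(remap[mesh@boundaryTriangles], ncol = 3)
  vd <- mesh@vertexData[sv, , drop = FALSE]
  vd$tetVertex <- sv
  rownames(vd) <- NULL
  new("TriangleSurface", vertices = mesh@vertices[sv, , drop = FALSE],
      triangles = tris, vertexData = vd)
}

#' Fill a closed surface with tetrahedra
#'
#' If the surface came from [extractSmoothSurface()], the conforming volume
#' mesh built alongside it is returned (its boundary equals the surface by
#' construction). For a stand-alone closed surface, a centroid-fan
#' tetrahedralization is used, which is valid for surfaces that are
#' star-shaped with respect to their centroid (verified via tet
#' orientations; an error is raised otherwise).
#'
#' @param s a closed, manifold, genus-0 [TriangleSurface-class].
#' @return a [TetrahedralMesh-class] whose boundary equals `s`.
#' @export
tetrahedralize <- function(s) {
  vm <- attr(s, "volumeMesh")
  if (!is.null(vm)) return(vm)
  ec <- edgeCounts(s@triangles)
  if (any(ec$counts != 2L))
    hsError("meshing", "surface is not closed/manifold")
  verts <- rbind(s@vertices, colMeans(s@vertices))
  ctr <- nrow(verts)
  tets <- cbind(s@triangles, ctr)
  vol <- tetVolumes(NULL, verts, tets)
  if (all(vol < 0)) {
    tets[, c(1, 2)] <- tets[, c(2, 1)]
    vol <- -vol
  }
  if (any(vol <= 0))
    hsError("meshing", "centroid-fan tetrahedralization failed: surface not star-shaped w.r.t. its centroid")
  vd <- s@vertexData
  if (!nrow(vd))
    vd <- data.frame(subfield = rep(NA_integer_, nrow(s@vertices)),
                     cap = NA_character_)
  vd <- rbind(vd, vd[1, , drop = FALSE])
  vd[nrow(vd), ] <- NA
  rownames(vd) <- NULL
  new("TetrahedralMesh", vertices = verts, tets = tets,
      boundaryTriangles = s@triangles, vertexData = vd)
}

#' Transfer voxel labels to mesh vertices
#'
#' Every vertex receives the subfield label of the nearest labeled voxel
#' (Euclidean distance in world mm via exact per-label distance transforms;
#' ties broken towards the lowest label code). Vertices farther than
#' `guardDistance` from any labeled voxel are still assigned but reported
#' in a warning. Cap tags (head/tail transitions) set during meshing are
#' preserved.
#'
#' @param mesh a [TetrahedralMesh-class] or [TriangleSurface-class].
#' @param vol the [LabelVolume-class] sharing the world frame.
#' @param guardDistance warning threshold in mm (default 3).
#' @return the input object with `subfield` filled in `vertexData`.
#' @export
transferLabels <- function(mesh, vol, guardDistance = 3) {
  L <- vol@labels
  bodyCodes <- unique(unname(L[intersect(bodySubfieldNames, names(L))]))
  voxdim <- voxelSizes(vol@affine)
  nlm <- nearestLabelMap(vol@data, bodyCodes, voxdim, withDist = TRUE)
  verts <- mesh@vertices
  idx <- round(worldToIndex(vol@affine, verts))
  n <- dim(vol@data)
  for (d in 1:3) idx[, d] <- pmin(pmax(idx[, d], 1), n[d])
  lab <- nlm$labels[idx]
  dist <- sqrt(nlm$dist[idx])
  far <- dist > guardDistance
  if (any(far))
    warning(sprintf("%d vertices farther than %.1f mm from any labeled voxel (max %.2f mm); nearest label assigned",
                    sum(far), guardDistance, max(dist)), call. = FALSE)
  if (!nrow(mesh@vertexData))
    mesh@vertexData <- data.frame(subfield = rep(NA_integer_, nrow(verts)),
                                  cap = NA_character_)
  mesh@vertexData$subfield <- as.integer(lab)
  nm <- names(L)[match(lab, L)]
  mesh@vertexData$subfieldName <- nm
  mesh
}

## Copy subfield labels from a volume mesh onto its extracted surface.
labelSurfaceFromMesh <- function(surf, mesh) {
  tv <- surf@vertexData$tetVertex
  surf@vertexData$subfield <- mesh@vertexData$subfield[tv]
  if (!is.null(mesh@vertexData$subfieldName))
    surf@vertexData$subfieldName <- mesh@vertexData$subfieldName[tv]
  surf
}
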