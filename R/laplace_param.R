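## laplace_param: P1 FEM Laplace solves on the tetrahedral mesh, the
## intrinsic coordinate system (harmonic map to the degenerated unit cube),
## and level-set surface extraction (marching tetrahedra).

## Per-tet P1 gradient operators: for tet (v1..v4) the gradients of the
## barycentric basis functions are constant; returns a list with the
## gradient rows for vertices 2..4 (3 matrices, ntet x 3); grad of vertex 1
## is minus their sum. Also the tet volumes.
tetGradients <- function(verts, tets) {
  a <- verts[tets[, 2], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  b <- verts[tets[, 3], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  cc <- verts[tets[, 4], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  ## det and adjugate of M = [a; b; c] (rows)
  det <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  det[abs(det) < 1e-300] <- 1e-300
  ## rows of inv(M)^T = cross products / det: grad(lambda_2) = (b x c)/det
  crossr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  g2 <- crossr(b, cc) / det
  g3 <- crossr(cc, a) / det
  g4 <- crossr(a, b) / det
  list(g = list(-(g2 + g3 + g4), g2, g3, g4), vol = det / 6)
}

## Sparse P1 stiffness matrix of the Laplacian on a tet mesh.
tetStiffness <- function(verts, tets) {
  tg <- tetGradients(verts, tets)
  nv <- nrow(verts)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (i in 1:4) for (j in 1:4) {
    ii <- c(ii, tets[, i]); jj <- c(jj, tets[, j])
    xx <- c(xx, abs(tg$vol) * rowSums(tg$g[[i]] * tg$g[[j]]))
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Solve a Laplace problem on the tetrahedral mesh
#'
#' Linear (P1) finite-element solution of Delta u = 0 with Dirichlet values
#' 0 on `zeroSet`, 1 on `oneSet`, and natural (Neumann) conditions
#' elsewhere. The reduced system is solved by sparse Cholesky; the relative
#' residual is checked against 1e-9. A discrete maximum principle violation
#' (possible with obtuse tets) is reported via attribute
#' `maxPrincipleViolation`, never silently clipped.
#'
#' @param mesh a [TetrahedralMesh-class].
#' @param zeroSet,oneSet disjoint non-empty vertex index sets.
#' @param axis axis tag for the resulting [ScalarField-class].
#' @return a [ScalarField-class].
#' @export
solveLaplaceFEM <- function(mesh, zeroSet, oneSet,
                            axis = "interior_exterior") {
  zeroSet <- as.integer(unique(zeroSet)); oneSet <- as.integer(unique(oneSet))
  if (!length(zeroSet) || !length(oneSet))
    hsError("laplace_param", "empty Dirichlet set")
  if (length(intersect(zeroSet, oneSet)))
    hsError("laplace_param", "overlapping Dirichlet sets")
  nv <- nrow(mesh@vertices)
  K <- tetStiffness(mesh@vertices, mesh@tets)
  fixed <- c(zeroSet, oneSet)
  uFix <- c(rep(0, length(zeroSet)), rep(1, length(oneSet)))
  free <- setdiff(seq_len(nv), fixed)
  u <- numeric(nv)
  u[fixed] <- uFix
  if (length(free)) {
    Kff <- K[free, free, drop = FALSE]
    b <- -as.numeric(K[free, fixed, drop = FALSE] %*% uFix)
    sol <- tryCatch(
      as.numeric(Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE,
                                                perm = TRUE), b)),
      error = function(e)
        hsError("laplace_param", "singular Laplace system (disconnected mesh?): %s",
                conditionMessage(e)))
    res <- sqrt(sum((as.numeric(Kff %*% sol) - b)^2)) /
      max(sqrt(sum(b^2)), 1e-300)
    if (res > 1e-9)
      hsError("laplace_param", "FEM solve did not reach tolerance (relative residual %.2e)", res)
    u[free] <- sol
  }
  viol <- max(0, max(u) - 1, -min(u))
  u[zeroSet] <- 0; u[oneSet] <- 1
  fld <- new("ScalarField", values = u, axis = axis,
             zeroSet = zeroSet, oneSet = oneSet)
  attr(fld, "maxPrincipleViolation") <- viol
  fld
}

#' Build the intrinsic coordinate system
#'
#' Three harmonic coordinates on the shared tetrahedral mesh: `uml` with
#' Dirichlet 0 on the medial curve C_m and 1 on the lateral curve C_l;
#' `uap` with 0 on the posterior and 1 on the anterior cut cross-section;
#' `uie` with 0 on the interior (SRLM-facing) and 1 on the exterior surface
#' patch. Orientation: medial->lateral, posterior->anterior and
#' interior->exterior all increasing. The coordinate Jacobian orientation is
#' checked: more than 1% inverted tets is an error.
#'
#' @param mesh the [TetrahedralMesh-class].
#' @param spec a [BoundarySpec-class] on the open surface.
#' @param surface the [OpenSurface-class] the spec refers to (its
#'   `vertexData$tetVertex` column maps to mesh vertices).
#' @return a [CoordinateSystem-class].
#' @export
buildCoordinateSystem <- function(mesh, spec, surface) {
  tv <- surface@vertexData$tetVertex
  if (is.null(tv))
    hsError("laplace_param", "surface does not map onto the volume mesh")
  tris <- surface@triangles
  intV <- unique(as.vector(tris[spec@interiorTriangles, , drop = FALSE]))
  extV <- unique(as.vector(tris[spec@exteriorTriangles, , drop = FALSE]))
  shared <- intersect(intV, extV)      # curve vertices: map degenerates here
  intV <- setdiff(intV, shared); extV <- setdiff(extV, shared)
  cap <- mesh@vertexData$cap
  antV <- which(!is.na(cap) & cap == "anterior")
  postV <- which(!is.na(cap) & cap == "posterior")
  uml <- solveLaplaceFEM(mesh, tv[spec@cm], tv[spec@cl], "medial_lateral")
  uap <- solveLaplaceFEM(mesh, postV, antV, "anterior_posterior")
  uie <- solveLaplaceFEM(mesh, tv[intV], tv[extV], "interior_exterior")
  cs <- new("CoordinateSystem", mesh = mesh, uml = uml, uap = uap, uie = uie)
  frac <- jacobianInvertedFraction(cs)
  if (frac > 0.01)
    hsError("laplace_param", "coordinate Jacobian inverted in %.1f%% of tets", 100 * frac)
  cs
}

## Fraction of tets whose (uml, uap, uie) gradient triple has the minority
## orientation sign.
jacobianInvertedFraction <- function(cs) {
  tg <- tetGradients(cs@mesh@vertices, cs@mesh@tets)
  gradOf <- function(v) {
    g <- tg$g
    g[[1]] * v[cs@mesh@tets[, 1]] + g[[2]] * v[cs@mesh@tets[, 2]] +
      g[[3]] * v[cs@mesh@tets[, 3]] + g[[4]] * v[cs@mesh@tets[, 4]]
  }
  a <- gradOf(cs@uml@values); b <- gradOf(cs@uap@values)
  cc <- gradOf(cs@uie@values)
  det <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  s <- sign(det)
  min(sum(s > 0), sum(s < 0)) / length(s)
}

## Per-tet constant gradient of one scalar field.
tetFieldGradient <- function(mesh, values) {
  tg <- tetGradients(mesh@vertices, mesh@tets)
  tg$g[[1]] * values[mesh@tets[, 1]] + tg$g[[2]] * values[mesh@tets[, 2]] +
    tg$g[[3]] * values[mesh@tets[, 3]] + tg$g[[4]] * values[mesh@tets[, 4]]
}

#' Extract a level-set surface of a coordinate field
#'
#' Marching tetrahedra on the per-tet linear interpolant: the level set of
#' a P1 field is a triangle/quad per crossing tet; quads are split by the
#' min-vertex-index rule. Cut points are deduplicated across tets, so the
#' result is a conforming triangle mesh. The other coordinate fields are
#' interpolated onto the level-set vertices, triangle normals point towards
#' increasing field values, and each triangle remembers its source tet
#' (attribute `parentTet`).
#'
#' @param cs a [CoordinateSystem-class].
#' @param axis "medial_lateral", "anterior_posterior" or
#'   "interior_exterior".
#' @param level iso-level strictly inside the field range.
#' @param checkConnected require a single connected component (the
#'   mid-surface contract).
#' @return a [TriangleSurface-class] with `uml`, `uap`, `uie` columns in
#'   `vertexData`.
#' @export
extractIsosurface <- function(cs, axis = "interior_exterior", level = 0.5,
                              checkConnected = (axis == "interior_exterior")) {
  fld <- switch(axis, medial_lateral = cs@uml,
                anterior_posterior = cs@uap, interior_exterior = cs@uie)
  u <- pmin(pmax(fld@values, 0), 1)     # clip max-principle excursions
  if (level <= min(u) || level >= max(u))
    hsError("laplace_param", "level %.3f outside field range", level)
  mesh <- cs@mesh
  tets <- mesh@tets
  s <- u - level
  s[s == 0] <- 1e-12
  pos <- s > 0
  npos <- pos[tets[, 1]] + pos[tets[, 2]] + pos[tets[, 3]] + pos[tets[, 4]]
  cross <- which(npos >= 1L & npos <= 3L)
  if (!length(cross))
    hsError("laplace_param", "empty level set")
  ## collect cut edges over crossing tets
  segsTri <- list(); segsQuad <- list()
  edgeKeyAll <- numeric(0)
  triList <- list()
  parent <- integer(0)
  perTet <- vector("list", length(cross))
  for (r in seq_along(cross)) {
    tt <- tets[cross[r], ]
    pp <- pos[tt]
    P <- tt[pp]; N <- tt[!pp]
    if (length(P) == 1L || length(P) == 3L) {
      apexSet <- if (length(P) == 1L) P else N
      others <- if (length(P) == 1L) N else P
      e <- cbind(rep(apexSet, 3L), others)
      perTet[[r]] <- list(type = 3L, edges = e)
    } else {
      e <- rbind(c(P[1], N[1]), c(P[2], N[1]), c(P[2], N[2]), c(P[1], N[2]))
      perTet[[r]] <- list(type = 4L, edges = e)
    }
  }
  allE <- do.call(rbind, lapply(perTet, `[[`, "edges"))
  keys <- pairKey(allE[, 1], allE[, 2])
  uk <- unique(keys)
  loN <- floor(uk / 2^26); hiN <- uk - loN * 2^26
  tcut <- (level - u[loN]) / (u[hiN] - u[loN])
  tcut <- pmin(pmax(tcut, 0), 1)
  cutPos <- mesh@vertices[loN, , drop = FALSE] * (1 - tcut) +
    mesh@vertices[hiN, , drop = FALSE] * tcut
  interp <- function(vals) vals[loN] * (1 - tcut) + vals[hiN] * tcut
  cutIdx <- match(keys, uk)
  ## assemble triangles
  ptr <- 0L
  for (r in seq_along(cross)) {
    ne <- nrow(perTet[[r]]$edges)
    ids <- cutIdx[ptr + seq_len(ne)]
    ptr <- ptr + ne
    if (perTet[[r]]$type == 3L) {
      triList[[length(triList) + 1L]] <- matrix(ids, 1, 3)
      parent <- c(parent, cross[r])
    } else {
      ## cyclic quad ids[1..4]; min-rule diagonal
      q <- ids
      tr <- if (min(q[1], q[3]) < min(q[2], q[4]))
        rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
      else rbind(q[c(2, 3, 4)], q[c(2, 4, 1)])
      triList[[length(triList) + 1L]] <- tr
      parent <- c(parent, cross[r], cross[r])
    }
  }
  tris <- do.call(rbind, triList)
  ## orient towards increasing field
  g <- tetFieldGradient(mesh, u)[parent, , drop = FALSE]
  nrm <- triangleNormals(cutPos, tris)
  flip <- rowSums(nrm * g) < 0
  if (any(flip)) tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
  vd <- data.frame(
    uml = interp(cs@uml@values), uap = interp(cs@uap@values),
    uie = interp(cs@uie@values))
  vd$subfield <- NA_integer_; vd$cap <- NA_character_
  surf <- new("TriangleSurface", vertices = cutPos, triangles = tris,
              vertexData = vd)
  if (checkConnected && max(triangleComponents(tris)) != 1L)
    hsError("laplace_param", "level set at %.2f is not a single connected component", level)
  attr(surf, "parentTet") <- parent
  surf
}
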