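## features: the N x M mid-surface grid, streamline thickness, mean
## curvature, geometric summary measures, modality projection, and the
## image-based (voxel) thickness oracle.

## Locate points in the (uml, uap) parameter plane of a level-set surface.
## Returns per point: triangle index, barycentric weights. Points that miss
## the parametrization get tri = NA unless a nearest-triangle fallback
## within `slack` applies.
paramLocate <- function(surfP, uq, vq, slack = 0.02) {
  P <- cbind(surfP@vertexData$uml, surfP@vertexData$uap)
  tris <- surfP@triangles
  p1 <- P[tris[, 1], , drop = FALSE]
  p2 <- P[tris[, 2], , drop = FALSE]
  p3 <- P[tris[, 3], , drop = FALSE]
  lo1 <- pmin(p1[, 1], p2[, 1], p3[, 1]); hi1 <- pmax(p1[, 1], p2[, 1], p3[, 1])
  lo2 <- pmin(p1[, 2], p2[, 2], p3[, 2]); hi2 <- pmax(p1[, 2], p2[, 2], p3[, 2])
  d <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  d[abs(d) < 1e-300] <- 1e-300
  n <- length(uq)
  triIdx <- rep(NA_integer_, n)
  W <- matrix(NA_real_, n, 3)
  for (q in seq_len(n)) {
    cand <- which(lo1 <= uq[q] + slack & hi1 >= uq[q] - slack &
                    lo2 <= vq[q] + slack & hi2 >= vq[q] - slack)
    if (!length(cand))
      cand <- which(lo1 <= uq[q] + 2 * slack & hi1 >= uq[q] - 2 * slack &
                      lo2 <= vq[q] + 2 * slack & hi2 >= vq[q] - 2 * slack)
    if (!length(cand)) next
    du <- uq[q] - p1[cand, 1]; dv <- vq[q] - p1[cand, 2]
    l2 <- ((p3[cand, 2] - p1[cand, 2]) * du -
             (p3[cand, 1] - p1[cand, 1]) * dv) / d[cand]
    l3 <- (-(p2[cand, 2] - p1[cand, 2]) * du +
             (p2[cand, 1] - p1[cand, 1]) * dv) / d[cand]
    l1 <- 1 - l2 - l3
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (any(inside)) {
      k <- cand[which(inside)[1]]
      i <- which(inside)[1]
      triIdx[q] <- k
      W[q, ] <- c(l1[i], l2[i], l3[i])
    } else {
      ## nearest fallback within slack: clamp barycentrics
      pen <- pmax(0, -l1) + pmax(0, -l2) + pmax(0, -l3)
      i <- which.min(pen)
      if (pen[i] <= 2 * slack) {
        lam <- pmax(c(l1[i], l2[i], l3[i]), 0)
        triIdx[q] <- cand[i]
        W[q, ] <- lam / sum(lam)
      }
    }
  }
  ## terminal fallback: snap to the nearest parameter-space vertex (folds
  ## near the degenerate curves can leave slim gaps in the triangulation)
  miss <- which(is.na(triIdx))
  if (length(miss)) {
    vtri <- integer(nrow(P))
    vtri[as.vector(t(tris))] <- rep(seq_len(nrow(tris)), each = 3)
    for (q in miss) {
      d2 <- (P[, 1] - uq[q])^2 + (P[, 2] - vq[q])^2
      v <- which.min(d2)
      if (sqrt(d2[v]) <= 2 * slack && vtri[v] > 0L) {
        k <- vtri[v]
        triIdx[q] <- k
        W[q, ] <- as.numeric(tris[k, ] == v)
      }
    }
  }
  list(tri = triIdx, w = W)
}

## Interpolate per-vertex values through a paramLocate result.
paramInterp <- function(surfP, loc, values) {
  tris <- surfP@triangles
  out <- rep(NA_real_, length(loc$tri))
  ok <- !is.na(loc$tri)
  tt <- tris[loc$tri[ok], , drop = FALSE]
  if (is.matrix(values)) {
    out <- matrix(NA_real_, length(loc$tri), ncol(values))
    out[ok, ] <- values[tt[, 1], , drop = FALSE] * loc$w[ok, 1] +
      values[tt[, 2], , drop = FALSE] * loc$w[ok, 2] +
      values[tt[, 3], , drop = FALSE] * loc$w[ok, 3]
  } else {
    out[ok] <- values[tt[, 1]] * loc$w[ok, 1] + values[tt[, 2]] * loc$w[ok, 2] +
      values[tt[, 3]] * loc$w[ok, 3]
  }
  out
}

#' Sample the regular N x M grid on the mid-surface
#'
#' Prescribes the cell-centered lattice u_ml = (i - 0.5)/N,
#' u_ap = (j - 0.5)/M (avoiding the degenerate boundary curves where the
#' harmonic map is non-bijective) and finds each grid point on the
#' mid-surface by parameter-space point location with barycentric
#' interpolation. The default 40 x 20 grid follows the standard convention
#' for hippocampal sheet analysis.
#'
#' @param mid the mid-surface from [extractIsosurface()] (u coordinates in
#'   `vertexData`).
#' @param N,M grid dimensions (medial/lateral x anterior/posterior).
#' @return a [ThicknessGrid-class] with positions filled, thickness and
#'   curvature still `NA`.
#' @export
sampleMidsurfaceGrid <- function(mid, N = hipposheetDefaults()$N,
                                 M = hipposheetDefaults()$M) {
  N <- as.integer(N); M <- as.integer(M)
  uml <- (seq_len(N) - 0.5) / N
  uap <- (seq_len(M) - 0.5) / M
  uq <- rep(uml, times = M)
  vq <- rep(uap, each = N)
  loc <- paramLocate(mid, uq, vq)
  if (anyNA(loc$tri)) {
    bad <- which(is.na(loc$tri))
    ij <- cbind(((bad - 1L) %% N) + 1L, ((bad - 1L) %/% N) + 1L)
    hsError("features",
            "grid point(s) not found in the parameter plane (fold-over?): first failing (i=%d, j=%d) of %d",
            ij[1, 1], ij[1, 2], length(bad))
  }
  pts <- paramInterp(mid, loc, mid@vertices)
  uie <- paramInterp(mid, loc, mid@vertexData$uie)
  g <- new("ThicknessGrid", N = N, M = M, uml = uml, uap = uap,
           points = pts, uie = uie,
           thickness = matrix(NA_real_, N, M),
           curvature = matrix(NA_real_, N, M),
           flags = matrix(0L, N, M))
  attr(g, "loc") <- loc
  attr(g, "parentTet") <- attr(mid, "parentTet")[loc$tri]
  g
}

## Face-neighbor topology of the tet mesh: neighbor tet per local face
## (0 = boundary), the per-vertex (volume-weighted) gradient of the
## interior/exterior field -- a continuous direction field that avoids
## tet-to-tet ping-pong across slivers -- and a step size of a quarter of
## the mean tet edge length.
tetTopology <- function(cs) {
  tets <- cs@mesh@tets
  verts <- cs@mesh@vertices
  nt <- nrow(tets)
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                 tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  fg <- faceGroups(faces)
  tid <- rep(seq_len(nt), 4L)
  lf <- rep(1:4, each = nt)
  o <- order(fg$group)
  nb <- matrix(0L, nt, 4)
  gs <- fg$group[o]
  dup <- which(gs[-1] == gs[-length(gs)])
  a <- o[dup]; b <- o[dup + 1L]
  nb[cbind(tid[a], lf[a])] <- tid[b]
  nb[cbind(tid[b], lf[b])] <- tid[a]
  tg <- tetGradients(verts, tets)
  gt <- tg$g[[1]] * cs@uie@values[tets[, 1]] +
    tg$g[[2]] * cs@uie@values[tets[, 2]] +
    tg$g[[3]] * cs@uie@values[tets[, 3]] +
    tg$g[[4]] * cs@uie@values[tets[, 4]]
  w <- abs(tg$vol)
  nv <- nrow(verts)
  vg <- matrix(0, nv, 3)
  wsum <- numeric(nv)
  for (c0 in 1:4) {
    for (d in 1:3) vg[, d] <- vg[, d] + tapply2(w * gt[, d], tets[, c0], nv)
    wsum <- wsum + tapply2(w, tets[, c0], nv)
  }
  vg <- vg / pmax(wsum, 1e-300)
  e1 <- verts[tets[, 2], ] - verts[tets[, 1], ]
  h <- 0.25 * mean(sqrt(rowSums(e1^2)))
  list(neighbor = nb, vgrad = vg, step = h)
}

## barycentric coordinates of p in tet (rows of 4)
.baryIn <- function(verts, tv, p) {
  M <- cbind(verts[tv[2], ] - verts[tv[1], ],
             verts[tv[3], ] - verts[tv[1], ],
             verts[tv[4], ] - verts[tv[1], ])
  lam234 <- tryCatch(as.numeric(solve(M, p - verts[tv[1], ])),
                     error = function(e) rep(NA_real_, 3))
  c(1 - sum(lam234), lam234)
}

## Trace the gradient streamline of u_ie from a point inside tet `tet0`
## in direction `dir` (+1 towards exterior, -1 towards interior) until the
## mesh boundary: RK2 on the vertex-interpolated gradient field, with
## tet-walk relocation after every step and exact clipping at the boundary.
traceHalfStreamline <- function(cs, topo, p, tet0, dir, maxSteps = 4000L) {
  verts <- cs@mesh@vertices
  tets <- cs@mesh@tets
  tet <- tet0
  h <- topo$step
  pts <- list(p)
  len <- 0
  gradAt <- function(tv, lam) {
    g <- lam[1] * topo$vgrad[tv[1], ] + lam[2] * topo$vgrad[tv[2], ] +
      lam[3] * topo$vgrad[tv[3], ] + lam[4] * topo$vgrad[tv[4], ]
    g
  }
  for (step in seq_len(maxSteps)) {
    tv <- tets[tet, ]
    lam <- .baryIn(verts, tv, p)
    if (anyNA(lam)) return(list(ok = FALSE, reason = "degenerate"))
    g1 <- gradAt(tv, lam)
    n1 <- sqrt(sum(g1^2))
    if (n1 < 1e-10) return(list(ok = FALSE, reason = "stalled"))
    d1 <- dir * g1 / n1
    lamM <- .baryIn(verts, tv, p + 0.5 * h * d1)
    g2 <- if (anyNA(lamM)) g1 else gradAt(tv, lamM)
    n2 <- sqrt(sum(g2^2))
    d2 <- if (n2 < 1e-10) d1 else dir * g2 / n2
    pn <- p + h * d2
    ## relocate pn by walking the face adjacency; clip at the boundary
    cur <- tet
    for (w in seq_len(100L)) {
      tvc <- tets[cur, ]
      lamN <- .baryIn(verts, tvc, pn)
      if (anyNA(lamN)) return(list(ok = FALSE, reason = "degenerate"))
      fc <- which.min(lamN)
      if (lamN[fc] >= -1e-9) {         # inside cur
        len <- len + h
        p <- pn; tet <- cur
        pts[[length(pts) + 1L]] <- p
        break
      }
      nxt <- topo$neighbor[cur, fc]
      if (nxt == 0L) {                 # boundary crossed: clip
        lamP <- .baryIn(verts, tvc, p)
        denom <- lamP[fc] - lamN[fc]
        tfrac <- if (abs(denom) > 1e-14) lamP[fc] / denom else 0
        tfrac <- min(max(tfrac, 0), 1)
        pEnd <- p + tfrac * (pn - p)
        pts[[length(pts) + 1L]] <- pEnd
        return(list(ok = TRUE, points = do.call(rbind, pts),
                    length = len + tfrac * h, tet = cur))
      }
      cur <- nxt
      if (w == 100L) return(list(ok = FALSE, reason = "lost"))
    }
  }
  list(ok = FALSE, reason = "step_budget")
}

#' Trace an interior/exterior streamline through a seed point
#'
#' Follows the normalized gradient of the interior/exterior coordinate in
#' both directions from the seed to the 0 and 1 boundaries. With P1
#' elements the gradient is constant per tet, so the streamline is traced
#' exactly tet-by-tet (no step-size error).
#'
#' @param cs a [CoordinateSystem-class].
#' @param seed 3D point (world mm) inside the mesh.
#' @param tet0 tet containing the seed (located by search when `NULL`).
#' @param topo cached [tetTopology()] (recomputed when `NULL`).
#' @return list with `points` (polyline interior -> exterior),
#'   `arcLength` (mm), and `ok`.
#' @export
traceStreamline <- function(cs, seed, tet0 = NULL, topo = NULL) {
  if (is.null(topo)) topo <- tetTopology(cs)
  if (is.null(tet0)) tet0 <- locateTet(cs@mesh, seed)
  if (is.na(tet0)) return(list(ok = FALSE, reason = "seed_outside"))
  dn <- traceHalfStreamline(cs, topo, seed, tet0, -1)
  up <- traceHalfStreamline(cs, topo, seed, tet0, +1)
  if (!isTRUE(dn$ok) || !isTRUE(up$ok))
    return(list(ok = FALSE,
                reason = paste(c(dn$reason, up$reason), collapse = "/")))
  pts <- rbind(dn$points[rev(seq_len(nrow(dn$points))), , drop = FALSE],
               up$points[-1, , drop = FALSE])
  list(ok = TRUE, points = pts, arcLength = dn$length + up$length)
}

## brute-force point location (used only for external seeds)
locateTet <- function(mesh, p) {
  verts <- mesh@vertices; tets <- mesh@tets
  ctr <- (verts[tets[, 1], ] + verts[tets[, 2], ] + verts[tets[, 3], ] +
            verts[tets[, 4], ]) / 4
  d2 <- (ctr[, 1] - p[1])^2 + (ctr[, 2] - p[2])^2 + (ctr[, 3] - p[3])^2
  for (tet in order(d2)[seq_len(min(200L, length(d2)))]) {
    tv <- tets[tet, ]
    M <- rbind(verts[tv[2], ] - verts[tv[1], ],
               verts[tv[3], ] - verts[tv[1], ],
               verts[tv[4], ] - verts[tv[1], ])
    lam234 <- tryCatch(as.numeric(solve(t(M), p - verts[tv[1], ])),
                       error = function(e) NULL)
    if (is.null(lam234)) next
    lam <- c(1 - sum(lam234), lam234)
    if (all(lam >= -1e-9)) return(tet)
  }
  NA_integer_
}

#' Fill the thickness map by streamline tracing
#'
#' Thickness at grid point (i, j) is the arc length of the
#' interior/exterior streamline through that point. Failed traces (flagged
#' in `flags`) are imputed from the 4-neighborhood mean; more than
#' `maxFailFraction` failures is an error.
#'
#' @param grid a [ThicknessGrid-class] with positions filled.
#' @param cs the [CoordinateSystem-class].
#' @param maxFailFraction tolerated fraction of failed traces.
#' @return the grid with `thickness` filled.
#' @export
computeThicknessMap <- function(grid, cs, maxFailFraction = 0.05) {
  topo <- tetTopology(cs)
  ptet <- attr(grid, "parentTet")
  N <- grid@N; M <- grid@M
  th <- matrix(NA_real_, N, M)
  for (k in seq_len(N * M)) {
    sl <- traceStreamline(cs, grid@points[k, ], tet0 = ptet[k], topo = topo)
    if (isTRUE(sl$ok)) th[k] <- sl$arcLength
  }
  fail <- is.na(th)
  if (mean(fail) > maxFailFraction)
    hsError("features", "%.1f%% of streamline traces failed", 100 * mean(fail))
  if (any(fail)) {
    for (k in which(fail)) {
      i <- ((k - 1L) %% N) + 1L; j <- ((k - 1L) %/% N) + 1L
      nb <- c(if (i > 1) th[i - 1, j], if (i < N) th[i + 1, j],
              if (j > 1) th[i, j - 1], if (j < M) th[i, j + 1])
      th[i, j] <- mean(nb, na.rm = TRUE)
    }
    grid@flags[fail] <- 1L
  }
  grid@thickness <- th
  grid
}

#' Signed mean curvature of the mid-surface, sampled on the grid
#'
#' Vertex mean curvature via the discrete mean-curvature-normal (cotangent)
#' operator, vertex-area normalized, signed positive where the surface is
#' convex towards the exterior (u_ie = 1) side. Open-boundary vertices are
#' filled from their interior neighborhood and flagged. Values are sampled
#' at the grid points by barycentric interpolation.
#'
#' @param mid the mid-surface (oriented towards increasing u_ie).
#' @param grid a [ThicknessGrid-class] sampled from `mid`.
#' @return the grid with `curvature` filled.
#' @export
computeCurvatureMap <- function(mid, grid) {
  H <- vertexMeanCurvature(mid@vertices, mid@triangles)
  loc <- attr(grid, "loc")
  hv <- paramInterp(mid, loc, H$value)
  grid@curvature <- matrix(hv, grid@N, grid@M)
  ## flag points interpolated from filled-in boundary vertices
  tb <- H$boundary[mid@triangles[loc$tri, 1]] |
    H$boundary[mid@triangles[loc$tri, 2]] |
    H$boundary[mid@triangles[loc$tri, 3]]
  grid@flags <- pmax(grid@flags, matrix(2L * tb, grid@N, grid@M))
  grid
}

## Per-vertex signed mean curvature (1/mm) on an oriented surface. The
## cotangent operator amplifies mesh ripple from marching-tetrahedra
## slivers, so the positions are relaxed on a copy (volume-conserving
## Taubin pairs) before differentiation and the scalar field is lightly
## diffused afterwards; both steps leave clean analytic meshes unchanged
## to within the stated tolerances.
vertexMeanCurvature <- function(verts, tris, smoothPositions = 10L,
                                smoothValue = 3L) {
  if (smoothPositions > 0L) {
    adj0 <- adjacencyFromEdges(surfaceEdges(tris), nrow(verts))
    deg0 <- pmax(Matrix::rowSums(adj0), 1)
    for (it in seq_len(smoothPositions))
      for (f in c(0.5, -0.53))
        verts <- verts + f * (as.matrix(adj0 %*% verts) / deg0 - verts)
  }
  L <- surfaceLaplacian(verts, tris, c(0, 0))
  Hvec <- as.matrix(L$K %*% verts) / (2 * L$mass)
  vn <- vertexNormals(verts, tris)
  H <- rowSums(Hvec * vn)
  if (smoothValue > 0L) {
    adj0 <- adjacencyFromEdges(surfaceEdges(tris), nrow(verts))
    deg0 <- pmax(Matrix::rowSums(adj0), 1)
    for (it in seq_len(smoothValue))
      H <- as.numeric(adj0 %*% H) / deg0
  }
  bl <- boundaryEdges(tris)
  isB <- rep(FALSE, nrow(verts))
  if (nrow(bl)) isB[unique(as.vector(bl))] <- TRUE
  if (any(isB)) {
    adj <- adjacencyFromEdges(surfaceEdges(tris), nrow(verts))
    Hfill <- H
    Hfill[isB] <- NA
    for (it in 1:10) {
      if (!anyNA(Hfill)) break
      m0 <- is.na(Hfill)
      x <- Hfill; x[m0] <- 0
      cnt <- as.numeric(adj %*% (!is.na(Hfill)))
      s <- as.numeric(adj %*% x)
      upd <- m0 & cnt > 0
      Hfill[upd] <- s[upd] / cnt[upd]
    }
    Hfill[is.na(Hfill)] <- 0
    H <- Hfill
  }
  list(value = H, boundary = isB)
}

## Arc length of the parameter line at fixed u_ap (varying u_ml) or fixed
## u_ml (varying u_ap) on a level surface.
paramLineLength <- function(surfP, fixed, value, nSamp = 101L,
                            span = c(0.005, 0.995)) {
  tpar <- seq(span[1], span[2], length.out = nSamp)
  if (fixed == "uap") { uq <- tpar; vq <- rep(value, nSamp) }
  else { uq <- rep(value, nSamp); vq <- tpar }
  loc <- paramLocate(surfP, uq, vq)
  pts <- paramInterp(surfP, loc, surfP@vertices)
  ok <- !is.na(pts[, 1])
  pts <- pts[ok, , drop = FALSE]
  if (nrow(pts) < 2) return(list(length = NA_real_, points = pts, ok = FALSE))
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  list(length = sum(seg), points = pts, ok = mean(ok) > 0.8, okMask = ok,
       par = tpar)
}

#' Geometric summary measures of the hippocampal body
#'
#' Derives the scalar shape measures: medial/lateral and anterior/posterior
#' extents (mean parameter-line lengths on the mid-surface), mean thickness,
#' per-row inner and outer cross-section lengths on the 0.01/0.99 level
#' surfaces (their sum is the circumference, their quotient the
#' interior/exterior ratio), per-row slice areas (the ribbon between
#' matched inner and outer cross-section points), the total exterior
#' surface area, and the 2D shape index (circumference / surface area).
#'
#' @param cs the [CoordinateSystem-class].
#' @param grid a [ThicknessGrid-class] with thickness filled.
#' @param mid the mid-surface.
#' @param innerLevel,outerLevel u_ie levels standing in for the inner and
#'   outer boundary surfaces (defaults 0.01 / 0.99, avoiding cap
#'   contamination of the raw mesh boundary).
#' @return a [GeometrySummary-class].
#' @export
geometricSummaries <- function(cs, grid, mid, innerLevel = 0.01,
                               outerLevel = 0.99) {
  inner <- extractIsosurface(cs, "interior_exterior", innerLevel,
                             checkConnected = FALSE)
  outer <- extractIsosurface(cs, "interior_exterior", outerLevel,
                             checkConnected = FALSE)
  rows <- grid@uap
  cols <- grid@uml
  lenX <- mean(vapply(rows, function(v)
    paramLineLength(mid, "uap", v)$length, numeric(1)), na.rm = TRUE)
  lenY <- mean(vapply(cols, function(u)
    paramLineLength(mid, "uml", u)$length, numeric(1)), na.rm = TRUE)
  nS <- 101L
  rowTab <- do.call(rbind, lapply(seq_along(rows), function(j) {
    li <- paramLineLength(inner, "uap", rows[j], nS)
    lo <- paramLineLength(outer, "uap", rows[j], nS)
    ## ratio from the central span: near the medial/lateral rims the inner
    ## and exterior surfaces meet, which contaminates the full-range arcs
    liC <- paramLineLength(inner, "uap", rows[j], nS, span = c(0.05, 0.95))
    loC <- paramLineLength(outer, "uap", rows[j], nS, span = c(0.05, 0.95))
    sliceArea <- NA_real_
    if (li$ok && lo$ok) {
      ok <- li$okMask & lo$okMask
      pi2 <- paramInterp(inner, paramLocate(inner, li$par[ok],
                                            rep(rows[j], sum(ok))),
                         inner@vertices)
      po2 <- paramInterp(outer, paramLocate(outer, li$par[ok],
                                            rep(rows[j], sum(ok))),
                         outer@vertices)
      good <- !is.na(pi2[, 1]) & !is.na(po2[, 1])
      pi2 <- pi2[good, , drop = FALSE]; po2 <- po2[good, , drop = FALSE]
      if (nrow(pi2) > 1) {
        k <- nrow(pi2)
        a1 <- triangleAreasFromPoints(pi2[-k, ], po2[-k, ], po2[-1, ])
        a2 <- triangleAreasFromPoints(pi2[-k, ], po2[-1, ], pi2[-1, ])
        ## the ribbon spans (outerLevel - innerLevel) of the cross-section
        sliceArea <- sum(a1 + a2) / (outerLevel - innerLevel)
      }
    }
    data.frame(j = j, uap = rows[j], innerLength = li$length,
               outerLength = lo$length,
               circumference = li$length + lo$length,
               ratio = liC$length / loC$length, sliceArea = sliceArea,
               ok = li$ok && lo$ok)
  }))
  okRows <- rowTab$ok & is.finite(rowTab$circumference)
  surfArea <- sum(triangleAreas(outer@vertices, outer@triangles))
  circ <- mean(rowTab$circumference[okRows])
  new("GeometrySummary",
      lengthX = lenX, lengthY = lenY,
      lengthZ = mean(grid@thickness, na.rm = TRUE),
      circumference = circ,
      interiorExteriorRatio = mean(rowTab$ratio[okRows]),
      surfaceArea = surfArea,
      shapeIndex = circ / surfArea,
      rowTable = rowTab)
}

triangleAreasFromPoints <- function(a, b, cc) {
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' Project a scalar volume onto the grid
#'
#' Trilinear sampling of a co-registered scalar image (fMRI, PET, ...) at
#' the mid-surface grid points; out-of-field points are `NA`.
#'
#' @param volArr 3D numeric array.
#' @param affine its voxel-to-world transform.
#' @param grid a [ThicknessGrid-class].
#' @return N x M matrix of sampled values.
#' @export
projectScalarVolume <- function(volArr, affine, grid) {
  idx <- worldToIndex(affine, grid@points)
  matrix(trilinear(volArr, idx), grid@N, grid@M)
}

#' Image-based thickness oracle on the voxel grid
#'
#' Independent, purely image-based thickness estimation: the
#' interior/exterior Laplace problem is solved by finite differences on the
#' voxel grid (world-mm spacing; Dirichlet 0/1 on the mask boundary voxels
#' nearest to the interior/exterior surface patches, no-flux elsewhere),
#' and streamlines of the resulting field are integrated through the given
#' seed points. Serves as the cross-method check for the mesh-based
#' thickness.
#'
#' @param m the [BodyMask-class].
#' @param o the [OpenSurface-class] carrying the patches.
#' @param spec the [BoundarySpec-class].
#' @param seeds world-mm points at which to report thickness (e.g.
#'   `gridPoints(grid)`).
#' @return list with `thickness` (per seed, mm), `u` (the voxel field),
#'   and the Dirichlet label array.
#' @export
voxelThicknessOracle <- function(m, o, spec, seeds) {
  mask <- m@mask
  n <- dim(mask)
  voxdim <- voxelSizes(m@affine)
  ## boundary voxels (6-neighborhood touching background)
  bg <- !mask
  touch <- array(FALSE, n)
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    touch <- touch | (mask & shiftArray(bg, d, TRUE))
  ## exclude cap-plane voxels from the Dirichlet boundary
  apKeep <- rep(TRUE, n[m@apAxis])
  apKeep[c(m@apRange[1], m@apRange[2])] <- FALSE
  bvox <- which(touch & slice1d(n, m@apAxis, apKeep))
  if (!length(bvox)) hsError("features", "no boundary voxels found")
  bw <- indexToWorld(m@affine, arrayInd(bvox, n))
  intPts <- o@vertices[unique(as.vector(
    o@triangles[spec@interiorTriangles, , drop = FALSE])), , drop = FALSE]
  extPts <- o@vertices[unique(as.vector(
    o@triangles[spec@exteriorTriangles, , drop = FALSE])), , drop = FALSE]
  dInt <- proxy_mindist(bw, intPts)
  dExt <- proxy_mindist(bw, extPts)
  lab <- array(0L, n)                  # 1 = interior Dirichlet, 2 = exterior
  lab[bvox] <- ifelse(dInt <= dExt, 1L, 2L)
  ## FD Laplace over foreground
  free <- which(mask & lab == 0L)
  u <- array(NA_real_, n)
  u[lab == 1L] <- 0; u[lab == 2L] <- 1
  fid <- array(0L, n); fid[free] <- seq_along(free)
  ii <- jj <- integer(0); xx <- numeric(0)
  bb <- numeric(length(free))
  diag0 <- numeric(length(free))
  dirs <- list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  hstep <- c(voxdim[1], voxdim[1], voxdim[2], voxdim[2], voxdim[3], voxdim[3])
  posFree <- arrayInd(free, n)
  for (k in seq_along(dirs)) {
    q <- posFree + rep(dirs[[k]], each = length(free))
    okq <- q[, 1] >= 1 & q[, 1] <= n[1] & q[, 2] >= 1 & q[, 2] <= n[2] &
      q[, 3] >= 1 & q[, 3] <= n[3]
    qi <- rep(1L, length(free))
    qi[okq] <- (q[okq, 3] - 1L) * n[1] * n[2] + (q[okq, 2] - 1L) * n[1] +
      q[okq, 1]
    inFg <- okq & mask[qi]
    w <- 1 / hstep[k]^2
    diag0[inFg] <- diag0[inFg] + w
    nbFree <- inFg & fid[qi] > 0L
    nbFix <- inFg & !nbFree
    ii <- c(ii, which(nbFree)); jj <- c(jj, fid[qi[nbFree]])
    xx <- c(xx, rep(-w, sum(nbFree)))
    if (any(nbFix)) bb[nbFix] <- bb[nbFix] + w * u[qi[nbFix]]
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_along(free)),
                            j = c(jj, seq_along(free)),
                            x = c(xx, diag0),
                            dims = c(length(free), length(free)))
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(A),
                                              LDL = FALSE, perm = TRUE), bb)),
    error = function(e)
      hsError("features", "voxel Laplace solve failed: %s",
              conditionMessage(e)))
  u[free] <- sol
  ## fill background by neighbor means for interpolation near the boundary
  ufill <- u
  for (it in 1:4) {
    m0 <- is.na(ufill)
    if (!any(m0)) break
    acc <- array(0, n); cnt <- array(0, n)
    filled <- !is.na(ufill)
    x <- ufill; x[!filled] <- 0
    for (d in dirs) {
      acc <- acc + shiftArray(x, d, 0)
      cnt <- cnt + shiftArray(filled, d, FALSE)
    }
    upd <- m0 & cnt > 0
    ufill[upd] <- acc[upd] / cnt[upd]
  }
  ufill[is.na(ufill)] <- 0.5
  ## gradient arrays (central differences in world mm)
  gx <- (shiftArray(ufill, c(-1,0,0), NA) - shiftArray(ufill, c(1,0,0), NA)) /
    (2 * voxdim[1])
  gy <- (shiftArray(ufill, c(0,-1,0), NA) - shiftArray(ufill, c(0,1,0), NA)) /
    (2 * voxdim[2])
  gz <- (shiftArray(ufill, c(0,0,-1), NA) - shiftArray(ufill, c(0,0,1), NA)) /
    (2 * voxdim[3])
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0; gz[is.na(gz)] <- 0
  maskD <- mask * 1.0
  thick <- integrateVoxelStreamlines(seeds, m@affine, ufill, gx, gy, gz,
                                     maskD, voxdim)
  list(thickness = thick, u = u, labels = lab)
}

## RK2 integration of +-grad(u) from all seeds simultaneously; paths run
## until they exit the digitized mask (trilinear indicator crossing 0.5,
## refined by linear interpolation over the last step), so lengths measure
## boundary-to-boundary distance through the segmentation.
integrateVoxelStreamlines <- function(seeds, affine, u, gx, gy, gz, maskD,
                                      voxdim) {
  step <- 0.3 * min(voxdim)
  total <- numeric(nrow(seeds))
  for (dir in c(-1, 1)) {
    p <- seeds
    active <- rep(TRUE, nrow(seeds))
    len <- numeric(nrow(seeds))
    mvPrev <- rep(1, nrow(seeds))
    for (it in seq_len(2000L)) {
      if (!any(active)) break
      idx <- worldToIndex(affine, p[active, , drop = FALSE])
      g <- cbind(trilinear(gx, idx), trilinear(gy, idx), trilinear(gz, idx))
      gn <- sqrt(rowSums(g^2))
      mv <- trilinear(maskD, idx)
      act <- which(active)
      out <- is.na(mv) | mv < 0.5 | gn < 1e-8
      if (any(out)) {
        ## refine the exit point: back up along the last step to the 0.5
        ## crossing of the mask indicator
        oi <- act[out]
        m0 <- mvPrev[oi]; m1 <- mv[out]
        m1[is.na(m1)] <- 0
        frac <- ifelse(m0 > 0.5 & m0 > m1, (m0 - 0.5) / pmax(m0 - m1, 1e-9),
                       0)
        len[oi] <- pmax(len[oi] - step * (1 - pmin(frac, 1)), 0)
        active[oi] <- FALSE
      }
      keep <- act[!out]
      if (!length(keep)) break
      mvPrev[keep] <- mv[!out]
      gk <- g[!out, , drop = FALSE] / gn[!out]
      mid <- p[keep, , drop = FALSE] + dir * 0.5 * step * gk
      idx2 <- worldToIndex(affine, mid)
      g2 <- cbind(trilinear(gx, idx2), trilinear(gy, idx2),
                  trilinear(gz, idx2))
      g2n <- sqrt(rowSums(g2^2))
      bad <- is.na(g2n) | g2n < 1e-8
      g2[bad, ] <- gk[bad, , drop = FALSE]
      g2n[bad] <- 1
      g2 <- g2 / g2n
      p[keep, ] <- p[keep, , drop = FALSE] + dir * step * g2
      len[keep] <- len[keep] + step
    }
    total <- total + len
  }
  total
}
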