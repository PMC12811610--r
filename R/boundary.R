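## boundary: cut the surface open at the head/tail transitions, compute the
## first eigenfunction of the curvature-aware anisotropic Laplace-Beltrami
## operator (Neumann boundary conditions), and derive the medial curve C_m,
## lateral curve C_l, and the interior/exterior patches.

#' Cut the closed body surface open at the head/tail transitions
#'
#' Removes the cap triangles (all three vertices tagged with the same cap),
#' leaving a surface with cylinder topology: Euler characteristic 0 and
#' exactly two boundary loops, the anterior and posterior cut rings.
#'
#' @param s a closed [TriangleSurface-class] with cap tags (from
#'   [extractSmoothSurface()]).
#' @return an [OpenSurface-class].
#' @export
cutOpenSurface <- function(s) {
  cap <- s@vertexData$cap
  if (is.null(cap) || !any(!is.na(cap)))
    hsError("boundary", "surface carries no anterior/posterior cap tags")
  t1 <- cap[s@triangles[, 1]]; t2 <- cap[s@triangles[, 2]]
  t3 <- cap[s@triangles[, 3]]
  isCapTri <- !is.na(t1) & !is.na(t2) & !is.na(t3) & t1 == t2 & t2 == t3
  tris <- s@triangles[!isCapTri, , drop = FALSE]
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(s@vertices))
  remap[used] <- seq_along(used)
  tris <- matrix(remap[tris], ncol = 3)
  vd <- s@vertexData[used, , drop = FALSE]
  rownames(vd) <- NULL
  loops <- boundaryLoopList(tris)
  if (length(loops) != 2L)
    hsError("boundary", "cutting produced %d boundary loops (expected 2): defective caps",
            length(loops))
  tag <- vapply(loops, function(l) {
    tg <- vd$cap[l]
    if (all(!is.na(tg)) && length(unique(tg)) == 1L) tg[1] else NA_character_
  }, character(1))
  if (!setequal(tag, c("anterior", "posterior")))
    hsError("boundary", "boundary loops are not cleanly anterior/posterior tagged")
  names(loops) <- tag
  o <- new("OpenSurface", vertices = s@vertices[used, , drop = FALSE],
           triangles = tris, vertexData = vd,
           boundaryLoops = loops[c("anterior", "posterior")])
  chi <- surfaceEulerCharacteristic(o)
  if (chi != 0L)
    hsError("boundary", "open surface is not a cylinder (Euler characteristic %d)", chi)
  o
}

## Per-face principal curvatures and directions: the face shape operator is
## fit by least squares to the vertex-normal differences along the three
## edges (projected into the face plane), then eigendecomposed. Curvature
## magnitudes are lightly diffused over the mesh for robustness.
faceCurvatureTensors <- function(verts, tris, smoothRounds = 2L) {
  m <- nrow(tris)
  fn <- triangleNormals(verts, tris)
  fl <- sqrt(rowSums(fn^2)); fl[fl == 0] <- 1
  nrm <- fn / fl
  vn <- vertexNormals(verts, tris)
  e1 <- verts[tris[, 2], ] - verts[tris[, 1], ]
  u <- e1 / pmax(sqrt(rowSums(e1^2)), 1e-12)
  v <- cbind(nrm[, 2] * u[, 3] - nrm[, 3] * u[, 2],
             nrm[, 3] * u[, 1] - nrm[, 1] * u[, 3],
             nrm[, 1] * u[, 2] - nrm[, 2] * u[, 1])
  ## accumulate 3x3 normal equations A'A (a,b,c) = A'rhs over the 3 edges
  M11 <- M12 <- M13 <- M22 <- M23 <- M33 <- r1 <- r2 <- r3 <- numeric(m)
  for (c0 in 1:3) {
    i <- tris[, c0]; j <- tris[, c0 %% 3 + 1]
    e <- verts[j, ] - verts[i, ]
    dn <- vn[j, ] - vn[i, ]
    eu <- rowSums(e * u); ev <- rowSums(e * v)
    du <- rowSums(dn * u); dv <- rowSums(dn * v)
    ## rows: [eu ev 0 | du], [0 eu ev | dv]
    M11 <- M11 + eu * eu
    M12 <- M12 + eu * ev
    M22 <- M22 + ev * ev + eu * eu
    M23 <- M23 + eu * ev
    M33 <- M33 + ev * ev
    r1 <- r1 + eu * du
    r2 <- r2 + ev * du + eu * dv
    r3 <- r3 + ev * dv
  }
  ## closed-form solve of the symmetric 3x3 systems (M13 = 0 by structure)
  det3 <- M11 * (M22 * M33 - M23 * M23) - M12 * (M12 * M33 - M23 * M13) +
    M13 * (M12 * M23 - M22 * M13)
  det3[abs(det3) < 1e-20] <- 1e-20
  a <- (r1 * (M22 * M33 - M23^2) - M12 * (r2 * M33 - M23 * r3) +
          M13 * (r2 * M23 - M22 * r3)) / det3
  b <- (M11 * (r2 * M33 - r3 * M23) - r1 * (M12 * M33 - M23 * M13) +
          M13 * (M12 * r3 - r2 * M13)) / det3
  cc <- (M11 * (M22 * r3 - M23 * r2) - M12 * (M12 * r3 - r2 * M13) +
           r1 * (M12 * M23 - M22 * M13)) / det3
  tr <- a + cc
  disc <- sqrt(pmax((a - cc)^2 / 4 + b^2, 0))
  k1 <- tr / 2 + disc
  k2 <- tr / 2 - disc
  swap <- abs(k2) > abs(k1)
  tmp <- k1[swap]; k1[swap] <- k2[swap]; k2[swap] <- tmp
  ## principal direction for k1 in the (u, v) frame
  w1 <- cbind(b, k1 - a)
  w2 <- cbind(k1 - cc, b)
  use2 <- rowSums(w2^2) > rowSums(w1^2)
  w <- w1; w[use2, ] <- w2[use2, ]
  wl <- sqrt(rowSums(w^2))
  flat <- wl < 1e-12
  w[flat, ] <- cbind(rep(1, sum(flat)), rep(0, sum(flat)))
  wl[flat] <- 1
  w <- w / wl
  d1 <- w[, 1] * u + w[, 2] * v
  d2 <- cbind(nrm[, 2] * d1[, 3] - nrm[, 3] * d1[, 2],
              nrm[, 3] * d1[, 1] - nrm[, 1] * d1[, 3],
              nrm[, 1] * d1[, 2] - nrm[, 2] * d1[, 1])
  ## diffuse curvature magnitudes face -> vertex -> face
  if (smoothRounds > 0L) {
    nv <- nrow(verts)
    for (r in seq_len(smoothRounds)) {
      for (nm in c("k1", "k2")) {
        val <- get(nm)
        vsum <- numeric(nv); vcnt <- numeric(nv)
        for (c0 in 1:3) {
          vsum <- vsum + tapply2(val, tris[, c0], nv)
          vcnt <- vcnt + tapply2(rep(1, m), tris[, c0], nv)
        }
        vval <- vsum / pmax(vcnt, 1)
        assign(nm, (vval[tris[, 1]] + vval[tris[, 2]] + vval[tris[, 3]]) / 3)
      }
    }
  }
  list(k1 = k1, k2 = k2, d1 = d1, d2 = d2)
}

#' Assemble the (anisotropic) surface Laplace-Beltrami operator
#'
#' Linear FEM stiffness matrix with a per-triangle conductivity tensor
#' expressed in the principal-curvature frame: weight
#' `1 / (1 + alpha1 * |k_max|)` across the high-curvature direction and
#' `1 + alpha2 * |k_min|` along it, so that diffusion is cheap along ridges
#' and expensive across them. With `anisotropy = c(0, 0)` the tensor is the
#' tangential identity and the matrix equals the cotangent Laplacian.
#' Returns the stiffness matrix `K` and the lumped (barycentric) mass
#' diagonal `mass`.
#'
#' @param verts,tris mesh arrays.
#' @param anisotropy numeric pair (alpha1, alpha2), in mm (inverse
#'   curvature) units.
#' @return list with sparse `K`, numeric `mass`, and the curvature tensors.
#' @export
surfaceLaplacian <- function(verts, tris, anisotropy = c(0, 0)) {
  m <- nrow(tris)
  nv <- nrow(verts)
  fn <- triangleNormals(verts, tris)
  A2 <- sqrt(rowSums(fn^2))            # 2 * area
  A2[A2 < 1e-14] <- 1e-14
  nrm <- fn / A2
  area <- A2 / 2
  if (any(anisotropy != 0)) {
    ct <- faceCurvatureTensors(verts, tris)
    w1 <- 1 / (1 + anisotropy[1] * abs(ct$k1))
    w2 <- 1 + anisotropy[2] * abs(ct$k2)
    D <- vector("list", 6)               # packed symmetric 3x3 per face
    comb <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
    for (q in 1:6) {
      i <- comb[q, 1]; j <- comb[q, 2]
      D[[q]] <- w1 * ct$d1[, i] * ct$d1[, j] + w2 * ct$d2[, i] * ct$d2[, j]
    }
    applyD <- function(g) cbind(
      D[[1]] * g[, 1] + D[[2]] * g[, 2] + D[[3]] * g[, 3],
      D[[2]] * g[, 1] + D[[4]] * g[, 2] + D[[5]] * g[, 3],
      D[[3]] * g[, 1] + D[[5]] * g[, 2] + D[[6]] * g[, 3])
  } else {
    applyD <- identity
  }
  ## P1 gradients: grad(phi_i) = (n x e_i) / (2A), e_i = edge opposite i
  grads <- vector("list", 3)
  for (i in 1:3) {
    jj <- i %% 3 + 1; kk <- jj %% 3 + 1
    e <- verts[tris[, kk], ] - verts[tris[, jj], ]
    g <- cbind(nrm[, 2] * e[, 3] - nrm[, 3] * e[, 2],
               nrm[, 3] * e[, 1] - nrm[, 1] * e[, 3],
               nrm[, 1] * e[, 2] - nrm[, 2] * e[, 1]) / A2
    grads[[i]] <- g
  }
  ii <- jj <- integer(0); xx <- numeric(0)
  Dg <- lapply(grads, applyD)
  for (i in 1:3) for (j in 1:3) {
    ii <- c(ii, tris[, i]); jj <- c(jj, tris[, j])
    xx <- c(xx, area * rowSums(grads[[i]] * Dg[[j]]))
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  mass <- numeric(nv)
  for (i in 1:3) mass <- mass + tapply2(area / 3, tris[, i], nv)
  list(K = K, mass = mass,
       curvature = if (any(anisotropy != 0)) ct else NULL)
}

## Smallest k eigenpairs of K f = lambda * diag(mass) f (symmetric, PSD).
## Dense path for small meshes, ARPACK shift-invert otherwise.
smallestEigenpairs <- function(K, mass, k) {
  n <- length(mass)
  sq <- 1 / sqrt(mass)
  S <- Matrix::Diagonal(x = sq) %*% K %*% Matrix::Diagonal(x = sq)
  S <- Matrix::forceSymmetric(S)
  if (n <= 900) {
    e <- eigen(as.matrix(S), symmetric = TRUE)
    ord <- order(e$values)[seq_len(k)]
    vals <- e$values[ord]
    vecs <- e$vectors[, ord, drop = FALSE] * sq
  } else {
    eps <- 1e-8 * mean(Matrix::diag(S))
    Ch <- Matrix::Cholesky(S + eps * Matrix::Diagonal(n), LDL = FALSE,
                           perm = TRUE)
    fn <- function(x, extra) as.numeric(Matrix::solve(Ch, x))
    ar <- igraph::arpack(fn, sym = TRUE,
                         options = list(n = n, nev = k,
                                        ncv = min(n, max(4 * k + 10, 40)),
                                        which = "LM", maxiter = 5000))
    mu <- ar$values
    vals <- 1 / mu - eps
    ord <- order(vals)
    vals <- vals[ord]
    vecs <- (if (is.matrix(ar$vectors)) ar$vectors else
               matrix(ar$vectors, ncol = 1))[, ord, drop = FALSE] * sq
  }
  ## mass-normalize
  for (c0 in seq_len(ncol(vecs))) {
    nrm2 <- sqrt(sum(mass * vecs[, c0]^2))
    vecs[, c0] <- vecs[, c0] / nrm2
  }
  list(values = pmax(vals, 0), vectors = vecs)
}

#' Eigenpairs of the (anisotropic) surface Laplacian
#'
#' Lowest `k` eigenpairs of the generalized problem K f = lambda M f with
#' natural (Neumann) boundary conditions, lumped mass. The first pair is the
#' constant mode with eigenvalue ~0.
#'
#' @param x an [OpenSurface-class] / [TriangleSurface-class], or a vertex
#'   matrix (then `tris` must be given).
#' @param anisotropy numeric pair, see [surfaceLaplacian()].
#' @param k number of eigenpairs.
#' @param tris triangle matrix when `x` is a vertex matrix.
#' @return list with `values`, `vectors` (mass-normalized columns), `K`,
#'   `mass`.
#' @export
surfaceSpectrum <- function(x, anisotropy = c(0, 0), k = 6L, tris = NULL) {
  if (is(x, "TriangleSurface")) { verts <- x@vertices; tris <- x@triangles }
  else verts <- x
  L <- surfaceLaplacian(verts, tris, anisotropy)
  e <- smallestEigenpairs(L$K, L$mass, k)
  c(e, list(K = L$K, mass = L$mass))
}

## Zero-level-set components of a vertex function on a surface.
## Returns per component: the crossing-edge ids, interpolated points, arc
## length, and which boundary rings it touches.
zeroSetComponents <- function(o, f) {
  f <- f + (f == 0) * 1e-12
  tris <- o@triangles
  verts <- o@vertices
  ec <- edgeCounts(tris)
  edges <- ec$edges
  ekey <- pairKey(edges[, 1], edges[, 2])
  crossing <- (f[edges[, 1]] > 0) != (f[edges[, 2]] > 0)
  if (!any(crossing)) return(list())
  cid <- integer(length(ekey)); cid[crossing] <- seq_len(sum(crossing))
  lookup <- function(a, b) {
    cid[match(pairKey(a, b), ekey)]
  }
  ## segment per triangle with two crossing edges
  s1 <- lookup(tris[, 1], tris[, 2])
  s2 <- lookup(tris[, 2], tris[, 3])
  s3 <- lookup(tris[, 3], tris[, 1])
  segs <- rbind(cbind(s1, s2), cbind(s2, s3), cbind(s3, s1))
  segs <- segs[segs[, 1] > 0 & segs[, 2] > 0, , drop = FALSE]
  ncross <- sum(crossing)
  ce <- edges[crossing, , drop = FALSE]
  tt <- f[ce[, 1]] / (f[ce[, 1]] - f[ce[, 2]])
  pts <- verts[ce[, 1], , drop = FALSE] * (1 - tt) +
    verts[ce[, 2], , drop = FALSE] * tt
  g <- igraph::make_empty_graph(ncross, directed = FALSE)
  g <- igraph::add_edges(g, t(segs))
  memb <- igraph::components(g)$membership
  ringA <- o@boundaryLoops$anterior
  ringP <- o@boundaryLoops$posterior
  bEdge <- ec$counts[crossing] == 1L   # crossing edges on the boundary
  lapply(seq_len(max(memb)), function(ci) {
    sel <- memb == ci
    eSel <- which(sel)
    sl <- segs[memb[segs[, 1]] == ci, , drop = FALSE]
    len <- sum(sqrt(rowSums((pts[sl[, 1], , drop = FALSE] -
                               pts[sl[, 2], , drop = FALSE])^2)))
    endpts <- ce[sel & bEdge, , drop = FALSE]
    list(edgeIds = eSel, edges = ce[eSel, , drop = FALSE],
         points = pts[eSel, , drop = FALSE],
         t = tt[eSel], length = len,
         touchesAnterior = any(endpts %in% ringA),
         touchesPosterior = any(endpts %in% ringP),
         segs = sl)
  })
}

#' First eigenfunction of the anisotropic Laplace-Beltrami operator
#'
#' Computes the lowest `K` non-constant eigenfunctions of the
#' curvature-aware anisotropic operator with Neumann conditions on the open
#' surface and selects the smallest-eigenvalue one whose zero level set
#' forms exactly two components, each joining the two boundary rings (the
#' configuration in which the zero curves can serve as medial/lateral
#' boundary curves). The sign is fixed so the mean over subiculum-labeled
#' vertices is positive.
#'
#' @param o an [OpenSurface-class].
#' @param anisotropy numeric pair (alpha1, alpha2); the default (stored in
#'   [hipposheetDefaults()]) attracts the zero sets to ridge lines.
#' @param K how many non-constant eigenfunctions to examine.
#' @return a [SurfaceEigenfunction-class].
#' @export
anisotropicLaplaceEigenfunction <- function(o,
                                            anisotropy = hipposheetDefaults()$anisotropy,
                                            K = 5L) {
  sp <- surfaceSpectrum(o, anisotropy, k = K + 1L)
  for (idx in 2:(K + 1L)) {
    f <- sp$vectors[, idx]
    comps <- zeroSetComponents(o, f)
    if (!length(comps)) next
    lens <- vapply(comps, `[[`, numeric(1), "length")
    big <- lens >= 0.1 * max(lens)
    r2r <- vapply(comps, function(cc) cc$touchesAnterior && cc$touchesPosterior,
                  logical(1))
    if (sum(big) == 2L && all(r2r[big])) {
      ## sign: positive mean over subiculum vertices when labeled
      nm <- o@vertexData$subfieldName
      if (!is.null(nm) && any(!is.na(nm))) {
        target <- which(nm %in% "subiculum")
        if (!length(target)) target <- which(!is.na(nm))
        if (mean(f[target]) < 0) f <- -f
      } else if (f[1] < 0) f <- -f
      return(new("SurfaceEigenfunction", values = as.numeric(f),
                 eigenvalue = sp$values[idx],
                 anisotropy = as.numeric(anisotropy), index = as.integer(idx)))
    }
  }
  hsError("boundary",
          "no eigenfunction among the first %d has a two-component ring-to-ring zero set", K)
}

## Snap one zero-set component to an ordered vertex path (the endpoint of
## each crossing edge with the smaller |f|), walking the segment chain.
zeroComponentToPath <- function(comp, f) {
  ids <- comp$edgeIds
  ## build chain order over local edge indices
  loc <- match(comp$segs, ids)
  dim(loc) <- dim(comp$segs)
  gg <- igraph::make_empty_graph(length(ids), directed = FALSE)
  gg <- igraph::add_edges(gg, t(loc))
  deg <- igraph::degree(gg)
  ends <- which(deg == 1L)
  ord <- if (length(ends) >= 2L) {
    as.integer(igraph::shortest_paths(gg, ends[1], ends[2])$vpath[[1]])
  } else seq_along(ids)
  snap <- ifelse(abs(f[comp$edges[, 1]]) <= abs(f[comp$edges[, 2]]),
                 comp$edges[, 1], comp$edges[, 2])
  path <- snap[ord]
  path[c(TRUE, diff(path) != 0)]
}

#' Derive the six boundary entities from the eigenfunction
#'
#' The two ring-to-ring zero-set components are snapped to vertex paths; the
#' one closer to the presubiculum/subiculum labels becomes the medial curve
#' C_m, the other the lateral curve C_l. The two surface patches separated
#' by the curves are classified by orientation: the patch whose normals
#' predominantly face the body centroid (the SRLM side) is the interior
#' patch.
#'
#' @param o the [OpenSurface-class].
#' @param f the selected [SurfaceEigenfunction-class].
#' @return a [BoundarySpec-class].
#' @export
deriveBoundarySpec <- function(o, f) {
  vals <- f@values
  comps <- zeroSetComponents(o, vals)
  lens <- vapply(comps, `[[`, numeric(1), "length")
  big <- which(lens >= 0.1 * max(lens))
  if (length(big) != 2L)
    hsError("boundary", "zero set does not have exactly two major components")
  paths <- lapply(comps[big], zeroComponentToPath, f = vals)
  ## distance of each curve to the medial labels
  if (is.null(o@vertexData$subfield) || all(is.na(o@vertexData$subfield)))
    hsError("boundary", "surface has no subfield labels; run transferLabels first")
  medialVerts <- medialVertsFor(o)
  dCurve <- vapply(paths, function(p) {
    d <- proxy_mindist(o@vertices[p, , drop = FALSE],
                       o@vertices[medialVerts, , drop = FALSE])
    mean(d)
  }, numeric(1))
  mIdx <- which.min(dCurve)
  cm <- paths[[mIdx]]; cl <- paths[[3 - mIdx]]
  ## patches: triangles by eigenfunction sign (majority over vertices)
  tris <- o@triangles
  tsign <- sign(vals[tris[, 1]] + vals[tris[, 2]] + vals[tris[, 3]])
  tsign[tsign == 0] <- 1
  patches <- list(which(tsign > 0), which(tsign < 0))
  if (!length(patches[[1]]) || !length(patches[[2]]))
    hsError("boundary", "eigenfunction does not separate the surface into two patches")
  ctr <- colMeans(o@vertices)
  inwardFrac <- vapply(patches, function(tset) {
    tt <- tris[tset, , drop = FALSE]
    nn <- triangleNormals(o@vertices, tt)
    fc <- (o@vertices[tt[, 1], ] + o@vertices[tt[, 2], ] +
             o@vertices[tt[, 3], ]) / 3
    mean(rowSums(nn * (rep(1, nrow(fc)) %o% ctr - fc)) > 0)
  }, numeric(1))
  if (abs(inwardFrac[1] - inwardFrac[2]) >= 0.05) {
    intIdx <- which.max(inwardFrac)
  } else {
    ## flat-sheet degeneracy: both patches face away from the centroid.
    ## Deterministic fallback: the inferior (lower mean z) patch is taken
    ## as interior; fatal only if that is ambiguous as well.
    mz <- vapply(patches, function(tset) {
      tt <- tris[tset, , drop = FALSE]
      mean((o@vertices[tt[, 1], 3] + o@vertices[tt[, 2], 3] +
              o@vertices[tt[, 3], 3]) / 3)
    }, numeric(1))
    zext <- diff(range(o@vertices[, 3]))
    if (abs(diff(mz)) < 0.05 * zext)
      hsError("boundary", "ambiguous interior/exterior patch assignment (margins %.2f vs %.2f)",
              inwardFrac[1], inwardFrac[2])
    warning("flat sheet: interior patch assigned to the inferior side by convention",
            call. = FALSE)
    intIdx <- which.min(mz)
  }
  new("BoundarySpec",
      cm = as.integer(cm), cl = as.integer(cl),
      anteriorRing = as.integer(o@boundaryLoops$anterior),
      posteriorRing = as.integer(o@boundaryLoops$posterior),
      interiorTriangles = as.integer(patches[[intIdx]]),
      exteriorTriangles = as.integer(patches[[3 - intIdx]]))
}

## vertices carrying medial (presubiculum/subiculum) labels; the label
## names are carried alongside the codes by transferLabels.
medialVertsFor <- function(o) {
  nm <- o@vertexData$subfieldName
  if (!is.null(nm) && any(nm %in% c("presubiculum", "subiculum")))
    return(which(nm %in% c("presubiculum", "subiculum")))
  ## fallback: lowest code band present
  sub <- o@vertexData$subfield
  codes <- sort(unique(sub[!is.na(sub)]))
  which(sub %in% codes[seq_len(min(2L, length(codes)))])
}

## min distance from each row of A to the point set B (chunked brute force)
proxy_mindist <- function(A, B, chunk = 2000L) {
  out <- numeric(nrow(A))
  bb <- t(B)
  b2 <- colSums(bb^2)
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ak <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ak^2), rep(1, ncol(bb))) - 2 * Ak %*% bb +
      outer(rep(1, nrow(Ak)), b2)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}
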