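## Triangle- and tet-mesh utilities shared across modules.

#' Signed tetrahedron volumes
#'
#' @param mesh a [TetrahedralMesh-class], or `NULL` when `verts`/`tets`
#'   are given directly.
#' @param verts,tets raw arrays (used when `mesh` is `NULL`).
#' @return numeric vector of signed volumes (positive = right-handed).
#' @export
tetVolumes <- function(mesh, verts = NULL, tets = NULL) {
  if (is(mesh, "TetrahedralMesh")) { verts <- mesh@vertices; tets <- mesh@tets }
  a <- verts[tets[, 2], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  b <- verts[tets[, 3], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  d <- verts[tets[, 4], , drop = FALSE] - verts[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

## Per-triangle (non-unit) normals and areas.
triangleNormals <- function(verts, tris) {
  e1 <- verts[tris[, 2], , drop = FALSE] - verts[tris[, 1], , drop = FALSE]
  e2 <- verts[tris[, 3], , drop = FALSE] - verts[tris[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

triangleAreas <- function(verts, tris) {
  n <- triangleNormals(verts, tris)
  0.5 * sqrt(rowSums(n^2))
}

## Angle-weighted unit vertex normals.
vertexNormals <- function(verts, tris) {
  fn <- triangleNormals(verts, tris)
  fl <- sqrt(rowSums(fn^2)); fl[fl == 0] <- 1
  fn <- fn / fl
  vn <- matrix(0, nrow(verts), 3)
  for (c in 1:3) {
    i <- tris[, c]; j <- tris[, c %% 3 + 1]; k <- tris[, (c + 1) %% 3 + 1]
    a <- verts[j, , drop = FALSE] - verts[i, , drop = FALSE]
    b <- verts[k, , drop = FALSE] - verts[i, , drop = FALSE]
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2))
    cosang <- pmin(pmax(rowSums(a * b) / (la * lb), -1), 1)
    w <- acos(cosang)
    for (d in 1:3)
      vn[, d] <- vn[, d] + unname(tapply2(w * fn[, d], i, nrow(verts)))
  }
  l <- sqrt(rowSums(vn^2)); l[l == 0] <- 1
  vn / l
}

## fast grouped sum into a fixed-length vector
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

## Exact numeric key for an unordered pair / triple of vertex indices.
pairKey <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  lo * 2^26 + hi
}

## Group faces (rows of vertex index triples, any order) into identical
## sets: returns for each face the id of its sorted-unique face and the
## count of occurrences of that face. Exact for any index size.
faceGroups <- function(faces) {
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  o <- order(lo, mid, hi)
  l2 <- lo[o]; m2 <- mid[o]; h2 <- hi[o]
  newgrp <- c(TRUE, l2[-1] != l2[-length(l2)] | m2[-1] != m2[-length(m2)] |
                h2[-1] != h2[-length(h2)])
  gid <- cumsum(newgrp)
  grp <- integer(nrow(faces))
  grp[o] <- gid
  cnt <- tabulate(gid)
  list(group = grp, count = cnt[grp])
}

## Unique undirected edges of a triangle set (matrix e x 2).
surfaceEdges <- function(tris) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  k <- pairKey(e[, 1], e[, 2])
  e[!duplicated(k), , drop = FALSE]
}

## Edges together with their triangle incidence counts.
edgeCounts <- function(tris) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  k <- pairKey(e[, 1], e[, 2])
  first <- !duplicated(k)
  uk <- k[first]
  cnt <- tabulate(match(k, uk), nbins = length(uk))
  list(edges = e[first, , drop = FALSE], counts = cnt)
}

#' Euler characteristic V - E + F of a triangle surface
#'
#' @param x a [TriangleSurface-class], or `NULL` with `tris` given.
#' @param tris triangle index matrix (used when `x` is not a surface).
#' @return integer Euler characteristic over the referenced vertices
#'   (2 for a closed genus-0 surface, 0 for an open cylinder).
#' @export
surfaceEulerCharacteristic <- function(x, tris = NULL) {
  if (is(x, "TriangleSurface")) tris <- x@triangles
  if (!nrow(tris)) return(NA_integer_)
  V <- length(unique(as.vector(tris)))
  E <- nrow(surfaceEdges(tris))
  as.integer(V - E + nrow(tris))
}

## TRUE if every edge belongs to at most two triangles.
isEdgeManifold <- function(tris) all(edgeCounts(tris)$counts <= 2L)

## Boundary edges (exactly one incident triangle), ordered as in the
## triangle (so the loop direction is consistent with triangle orientation).
boundaryEdges <- function(tris) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  k <- pairKey(e[, 1], e[, 2])
  first <- !duplicated(k)
  uk <- k[first]
  cnt <- tabulate(match(k, uk), nbins = length(uk))
  e[first, , drop = FALSE][cnt == 1L, , drop = FALSE]
}

## Ordered closed boundary loops (list of vertex index vectors). Assumes a
## manifold surface: each boundary vertex has one outgoing boundary edge.
boundaryLoopList <- function(tris) {
  be <- boundaryEdges(tris)
  if (!nrow(be)) return(list())
  if (anyDuplicated(be[, 1]))
    hsError("meshing", "non-manifold boundary: vertex on more than two boundary edges")
  maxv <- max(be)
  nxt <- rep(NA_integer_, maxv)
  nxt[be[, 1]] <- be[, 2]
  visited <- logical(maxv)
  loops <- list()
  for (s in be[, 1]) {
    if (visited[s]) next
    loop <- integer(0); v <- s
    repeat {
      loop <- c(loop, v); visited[v] <- TRUE
      v <- nxt[v]
      if (is.na(v) || visited[v]) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

## Enclosed volume of a closed, outward-oriented surface (divergence thm).
enclosedVolume <- function(verts, tris) {
  v1 <- verts[tris[, 1], , drop = FALSE]
  v2 <- verts[tris[, 2], , drop = FALSE]
  v3 <- verts[tris[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

## Connected components of the triangle graph (via shared edges); returns
## a component id per triangle.
triangleComponents <- function(tris) {
  e <- rbind(cbind(tris[, 1], tris[, 2]), cbind(tris[, 2], tris[, 3]),
             cbind(tris[, 3], tris[, 1]))
  k <- pairKey(e[, 1], e[, 2])
  tid <- rep(seq_len(nrow(tris)), 3L)
  o <- order(k)
  k <- k[o]; tid <- tid[o]
  same <- which(k[-1] == k[-length(k)])
  g <- igraph::make_empty_graph(nrow(tris), directed = FALSE)
  if (length(same))
    g <- igraph::add_edges(g, rbind(tid[same], tid[same + 1L]))
  igraph::components(g)$membership
}

## Sparse vertex adjacency (0/1) from an edge matrix.
adjacencyFromEdges <- function(edges, n) {
  Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                       j = c(edges[, 2], edges[, 1]),
                       x = 1, dims = c(n, n))
}

## Neighbor-mean positions under a sparse adjacency.
neighborMeans <- function(adj, P) {
  deg <- Matrix::rowSums(adj)
  deg[deg == 0] <- 1
  as.matrix(adj %*% P) / deg
}
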