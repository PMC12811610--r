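## 3D array helpers: shifting, morphology, smoothing, connected components,
## exact Euclidean distance transforms, trilinear sampling.

## Stage-tagged error used across the pipeline so the orchestrator can map
## failures to documented exit codes.
hsError <- function(stage, msg, ...) {
  stop(structure(class = c("hipposheetError", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1),
                      stage = stage)))
}

## Shift a 3D logical/numeric array by (dx,dy,dz), padding with `fill`.
shiftArray <- function(a, d, fill = 0) {
  n <- dim(a)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(n[ax]) - d[ax]
    i[i < 1L | i > n[ax]] <- NA_integer_
    i
  })
  out <- a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out[is.na(out)] <- fill
  dim(out) <- n
  out
}

## Face-neighborhood (6-connected) binary dilation / erosion / closure.
dilate6 <- function(a) {
  out <- a
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out | shiftArray(a, d, FALSE)
  out
}

erode6 <- function(a) {
  out <- a
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out & shiftArray(a, d, TRUE)
  out
}

## Repeated morphological closure (dilation then erosion) with the
## 6-connected structuring element. Operates inside a 1-voxel zero pad so
## dilation cannot run off the array.
closeMask <- function(mask, iterations = 2L) {
  if (iterations < 1L) return(mask)
  n <- dim(mask)
  pad <- iterations + 1L
  big <- array(FALSE, n + 2L * pad)
  big[pad + seq_len(n[1]), pad + seq_len(n[2]), pad + seq_len(n[3])] <- mask
  for (i in seq_len(iterations)) big <- dilate6(big)
  for (i in seq_len(iterations)) big <- erode6(big)
  big[pad + seq_len(n[1]), pad + seq_len(n[2]), pad + seq_len(n[3])]
}

## Connected components of a logical array. connectivity 6 or 26.
## Returns an integer array of component ids (0 = off) plus count.
arrayComponents <- function(a, connectivity = 6L) {
  idx <- which(a)
  if (!length(idx))
    return(list(labels = array(0L, dim(a)), n = 0L, sizes = integer()))
  n <- dim(a)
  pos <- arrayInd(idx, n)
  id <- array(0L, n)
  id[idx] <- seq_along(idx)
  if (connectivity == 6L) {
    dirs <- list(c(1,0,0), c(0,1,0), c(0,0,1))
  } else {
    dirs <- list()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      d <- c(dx, dy, dz)
      if (any(d != 0) && (dx > 0 || (dx == 0 && (dy > 0 || (dy == 0 && dz > 0)))))
        dirs <- c(dirs, list(d))
    }
  }
  edges <- list()
  for (d in dirs) {
    q <- pos + rep(d, each = nrow(pos))
    ok <- q[, 1] >= 1 & q[, 1] <= n[1] & q[, 2] >= 1 & q[, 2] <= n[2] &
      q[, 3] >= 1 & q[, 3] <= n[3]
    if (!any(ok)) next
    j <- id[q[ok, , drop = FALSE]]
    keep <- j > 0L
    if (any(keep))
      edges[[length(edges) + 1L]] <- cbind(which(ok)[keep], j[keep])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  lab <- array(0L, n)
  lab[idx] <- comp$membership
  list(labels = lab, n = comp$no, sizes = as.integer(comp$csize))
}

## Separable Gaussian smoothing of a 3D array; sigma in voxels per axis,
## replicate padding at the edges.
gaussianSmooth3D <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  out <- a * 1.0
  n <- dim(a)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    k <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-k, k))^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, n)
    for (off in -k:k) {
      i <- pmin(pmax(seq_len(n[ax]) + off, 1L), n[ax])
      sl <- switch(ax,
                   out[i, , , drop = FALSE],
                   out[, i, , drop = FALSE],
                   out[, , i, drop = FALSE])
      acc <- acc + w[off + k + 1L] * sl
    }
    out <- acc
  }
  out
}

## Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
## 1D pass. f = input costs (0 at sources, Inf elsewhere), h = sample step.
dt1d <- function(f, h) {
  n <- length(f)
  fin <- which(is.finite(f))
  ## lower envelope over the finite parabolas only (infinite ones never win)
  v <- integer(length(fin)); z <- numeric(length(fin) + 1L)
  k <- 1L; v[1] <- fin[1]; z[1] <- -Inf; z[2] <- Inf
  if (length(fin) > 1L) for (q in fin[-1]) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + (q * h)^2) - (f[vk] + (vk * h)^2)) / (2 * h * (q - vk))
      if (s <= z[k]) k <- k - 1L
      else { k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf; break }
    }
  }
  d <- numeric(n)
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q * h) k <- k + 1L
    d[q] <- (q * h - v[k] * h)^2 + f[v[k]]
  }
  d
}

## 3D squared EDT from a source mask, with world voxel sizes (mm).
distanceTransform3D <- function(src, voxdim) {
  n <- dim(src)
  f <- array(Inf, n)
  f[src] <- 0
  ## pass along axis 1
  for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    col <- f[, j, k]
    if (any(is.finite(col))) f[, j, k] <- dt1d(col, voxdim[1])
  }
  for (i in seq_len(n[1])) for (k in seq_len(n[3])) {
    col <- f[i, , k]
    if (any(is.finite(col))) f[i, , k] <- dt1d(col, voxdim[2])
  }
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) {
    col <- f[i, j, ]
    if (any(is.finite(col))) f[i, j, ] <- dt1d(col, voxdim[3])
  }
  f
}

## For every voxel, the code of the nearest voxel carrying one of `codes`
## (Euclidean distance in world mm; ties broken by lowest code).
nearestLabelMap <- function(lab, codes, voxdim, withDist = FALSE) {
  best <- array(Inf, dim(lab))
  out <- array(0L, dim(lab))
  for (code in sort(codes)) {
    src <- lab == code
    if (!any(src)) next
    d <- distanceTransform3D(src, voxdim)
    upd <- d < best - 1e-9
    best[upd] <- d[upd]
    out[upd] <- code
  }
  if (withDist) list(labels = out, dist = best) else out
}

## Trilinear interpolation of a 3D array at continuous *R index* positions
## (1-based). Points outside the array return NA.
trilinear <- function(a, pts) {
  n <- dim(a)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 1 & x <= n[1] & y >= 1 & y <= n[2] & z >= 1 & z <= n[3]
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), n[1] - 1L); y0 <- pmin(floor(y), n[2] - 1L)
  z0 <- pmin(floor(z), n[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  g <- function(i, j, k) a[cbind(i, j, k)]
  v <- g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    g(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    g(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    g(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    g(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    g(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    g(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}

## world <-> voxel (R 1-based index) conversions under the NIfTI convention.
worldToIndex <- function(affine, pts) {
  inv <- solve(affine)
  p <- cbind(pts, 1) %*% t(inv)
  p[, 1:3, drop = FALSE] + 1
}

indexToWorld <- function(affine, idx) {
  p <- cbind(idx - 1, 1) %*% t(affine)
  p[, 1:3, drop = FALSE]
}
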