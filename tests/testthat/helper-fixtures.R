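## Shared fixtures, built once per test session (all generated in code).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## full pipeline on the default slab phantom (a=20, b=30, t=3)
slabRun <- function() fixture("slabRun", function() {
  ph <- makeSlabPhantom()
  out <- file.path(tempdir(), "slab_run")
  res <- suppressWarnings(runPipeline(ph$volume, out, dialect = "phantom"))
  stopifnot(res$exitCode == 0L)
  list(phantom = ph, res = res, outDir = out)
})

## full pipeline on the varying-thickness shell (t(theta) = 2 + sin theta)
shellSinRun <- function() fixture("shellSinRun", function() {
  ph <- makeCurvedShellPhantom(
    phantomSpec(thicknessFn = function(theta, y) 2 + sin(theta)))
  out <- file.path(tempdir(), "shell_sin_run")
  res <- runPipeline(ph$volume, out, dialect = "phantom")
  stopifnot(res$exitCode == 0L)
  list(phantom = ph, res = res, outDir = out)
})

## full pipeline on the constant-thickness shell (t = 2.5, R = 15, 180 deg)
shellConstRun <- function() fixture("shellConstRun", function() {
  ph <- makeCurvedShellPhantom(phantomSpec())
  out <- file.path(tempdir(), "shell_const_run")
  res <- runPipeline(ph$volume, out, dialect = "phantom")
  stopifnot(res$exitCode == 0L)
  list(phantom = ph, res = res, outDir = out)
})

## small shell for cheaper property tests (not a study condition)
smallShellRun <- function() fixture("smallShellRun", function() {
  ph <- makeCurvedShellPhantom(
    phantomSpec(R = 12, L = 15, arc = c(0, 2.2),
                thicknessFn = function(theta, y) rep(2.5, length(theta))))
  out <- file.path(tempdir(), "small_shell_run")
  res <- runPipeline(ph$volume, out, dialect = "phantom")
  stopifnot(res$exitCode == 0L)
  list(phantom = ph, res = res, outDir = out)
})

## per-grid-point ground-truth thickness of a shell run
shellTruthGrid <- function(run) {
  g <- run$res$grid
  tr <- run$phantom$truth
  th <- tr$thetaFromUml(g@uml)
  list(thickness = matrix(tr$thickness(rep(th, g@M),
                                       rep(g@uap * tr$L, each = g@N)),
                          g@N, g@M),
       valid = matrix(rep(tr$validUml(g@uml), g@M), g@N, g@M))
}

## brute-force Benjamini-Hochberg step-up (independent oracle)
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

## hand-built 12-triangle unit cube surface (outward oriented)
unitCubeSurface <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tris <- rbind(
    c(1, 3, 2), c(2, 3, 4),     # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),     # z = 1 (+z)
    c(1, 2, 5), c(2, 6, 5),     # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),     # y = 1 (+y)
    c(1, 5, 3), c(3, 5, 7),     # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6))     # x = 1 (+x)
  new("TriangleSurface", vertices = v, triangles = tris,
      vertexData = data.frame(subfield = rep(NA_integer_, 8),
                              cap = NA_character_))
}

## voxelized ball body mask (isotropic 1 mm, radius in voxels)
ballMask <- function(r = 10, n = 2 * r + 7) {
  ctr <- (n + 1) / 2
  pos <- arrayInd(seq_len(n^3), c(n, n, n))
  mask <- array(sqrt(rowSums((pos - ctr)^2)) <= r, c(n, n, n))
  new("BodyMask", mask = mask, affine = diag(4), apAxis = 2L,
      apRange = c(1L, as.integer(n)), anteriorEnd = 2L)
}

## independently assembled cotangent Laplacian (oracle for the isotropic
## reduction of the anisotropic operator)
cotanLaplacianOracle <- function(verts, tris) {
  nv <- nrow(verts)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (c0 in 1:3) {
    i <- tris[, c0]; j <- tris[, c0 %% 3 + 1]; k <- tris[, (c0 + 1) %% 3 + 1]
    a <- verts[i, ] - verts[k, ]; b <- verts[j, ] - verts[k, ]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    cot <- rowSums(a * b) / sqrt(rowSums(cr^2))
    ii <- c(ii, i, j, i, j); jj <- c(jj, j, i, i, j)
    xx <- c(xx, -cot / 2, -cot / 2, cot / 2, cot / 2)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
}

## write a minimal big-endian MGH/MGZ volume (test fixture generator)
writeMGZFixture <- function(arr, spacing, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(1L, con, size = 4, endian = "big")
  writeBin(as.integer(c(dim(arr), 1L)), con, size = 4, endian = "big")
  writeBin(c(1L, 0L), con, size = 4, endian = "big")   # type int, dof
  writeBin(1L, con, size = 2, endian = "big")          # goodRAS
  writeBin(as.numeric(spacing), con, size = 4, endian = "big")
  writeBin(as.numeric(diag(3)), con, size = 4, endian = "big")
  writeBin(as.numeric(dim(arr) * spacing / 2), con, size = 4, endian = "big")
  writeBin(raw(284 - (4 * 7 + 2 + 4 * 15)), con)
  writeBin(as.integer(arr), con, size = 4, endian = "big")
  invisible(path)
}
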