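## manual coordinate system on a box (shared with test-laplace)
boxCS <- function(a = 1, b = 1, cc = 1, n = 8L) {
  bx <- makeBoxTetMesh(a, b, cc, n, n, n)
  v <- vertices(bx)
  face <- function(d, val) which(abs(v[, d] - val) < 1e-12)
  new("CoordinateSystem", mesh = bx,
      uml = solveLaplaceFEM(bx, face(1, 0), face(1, a), "medial_lateral"),
      uap = solveLaplaceFEM(bx, face(2, 0), face(2, b), "anterior_posterior"),
      uie = solveLaplaceFEM(bx, face(3, 0), face(3, cc), "interior_exterior"))
}

test_that("grid sampling hits the exact lattice on an affine box", {
  cs <- boxCS()
  mid <- extractIsosurface(cs, "interior_exterior", 0.5)
  g <- sampleMidsurfaceGrid(mid, 2L, 2L)
  expect_equal(gridDim(g), c(2L, 2L))
  pts <- gridPoints(g)
  expect_equal(sort(unique(round(pts[, 1], 9))), c(0.25, 0.75))
  expect_equal(sort(unique(round(pts[, 2], 9))), c(0.25, 0.75))
  expect_lt(max(abs(pts[, 3] - 0.5)), 1e-9)
  ## the prescribed lattice is the cell-centered one
  expect_equal(g@uml, c(0.25, 0.75))
  expect_lt(max(abs(g@uie - 0.5)), 0.02)
})

test_that("the default grid follows the 40 x 20 convention", {
  expect_equal(hipposheetDefaults()$N, 40L)
  expect_equal(hipposheetDefaults()$M, 20L)
  run <- shellConstRun()
  expect_equal(gridDim(run$res$grid), c(40L, 20L))
})

test_that("streamlines are straight and exact on the slab geometry", {
  cs <- boxCS(cc = 3)        # 1 x 1 x 3 box, u_ie along z
  sl <- traceStreamline(cs, c(0.5, 0.5, 1.5))
  expect_true(sl$ok)
  expect_equal(sl$arcLength, 3, tolerance = 1e-3)
  ## retrace from the recovered midpoint reproduces the endpoints
  midpt <- sl$points[which.min(abs(sl$points[, 3] - 1.5)), ]
  sl2 <- traceStreamline(cs, midpt)
  expect_equal(sl2$arcLength, sl$arcLength, tolerance = 1e-3)
})

test_that("annulus streamlines are radial with the analytic length", {
  an <- makeAnnulusTetMesh(r0 = 5, r1 = 10, h = 4, phi = pi / 2,
                           nr = 12L, nphi = 24L, nz = 4L)
  w <- attr(an, "wallVertices")
  uie <- solveLaplaceFEM(an, w$inner, w$outer, "interior_exterior")
  d1 <- uie; d1@axis <- "medial_lateral"
  d2 <- uie; d2@axis <- "anterior_posterior"
  cs <- new("CoordinateSystem", mesh = an, uml = d1, uap = d2, uie = uie)
  seed <- c(7.5 * cos(pi / 4), 7.5 * sin(pi / 4), 2)
  sl <- traceStreamline(cs, seed)
  expect_true(sl$ok)
  expect_lt(abs(sl$arcLength - 5) / 5, 0.02)
})

test_that("thickness maps recover the phantom fields", {
  ## slab: constant 3 mm
  slab <- slabRun()
  g <- slab$res$grid
  valid <- slab$phantom$truth$validUml(g@uml)
  expect_lt(abs(mean(thicknessValues(g)[valid, ]) - 3) / 3, 0.02)
  expect_lt(max(abs(thicknessValues(g)[valid, ] - 3)), 0.05)
  ## varying shell: per-point recovery in the valid region
  shell <- shellSinRun()
  tg <- shellTruthGrid(shell)
  est <- thicknessValues(shell$res$grid)
  rel <- abs(est - tg$thickness) / tg$thickness
  expect_lt(median(rel[tg$valid]), 0.05)
  expect_gt(cor(as.numeric(est), as.numeric(tg$thickness)), 0.95)
  ## constant shell: thickness independent of the longitudinal row
  cst <- shellConstRun()
  gc <- thicknessValues(cst$res$grid)
  validC <- cst$phantom$truth$validUml(cst$res$grid@uml)
  rowVar <- apply(gc[validC, ], 1, stats::var)
  expect_lt(max(rowVar) / mean(gc[validC, ]), 5e-3)
})

test_that("mean curvature matches cylinder, plane and sphere", {
  tube <- makeTubeSurface(r = 5, hh = 20)
  H <- hipposheet:::vertexMeanCurvature(vertices(tube), triangles(tube))
  interior <- abs(vertices(tube)[, 3] - 10) < 7
  expect_lt(abs(mean(H$value[interior]) - 1 / 10) / (1 / 10), 0.05)
  rect <- makeRectangleSurface()
  Hp <- hipposheet:::vertexMeanCurvature(vertices(rect), triangles(rect))
  expect_lt(max(abs(Hp$value[!Hp$boundary])), 1e-6)
  sph <- makeSphereSurface(r = 5)
  Hs <- hipposheet:::vertexMeanCurvature(vertices(sph), triangles(sph))
  expect_lt(abs(mean(Hs$value) - 1 / 5) / (1 / 5), 0.05)
  ## phantom mid-surface: positive (convex towards exterior), ~1/(2R)
  run <- shellConstRun()
  cv <- curvatureValues(run$res$grid)
  valid <- run$phantom$truth$validUml(run$res$grid@uml)
  expect_lt(abs(mean(cv[valid, ]) - 1 / 30) / (1 / 30), 0.1)
})

test_that("geometric summaries match the analytic phantoms", {
  slab <- slabRun()
  s <- slab$res$summary
  tr <- slab$phantom$truth
  expect_lt(abs(s@lengthX - tr$a) / tr$a, 0.02)
  expect_lt(abs(s@lengthY - tr$b) / tr$b, 0.02)
  valid <- tr$validUml(slab$res$grid@uml)
  expect_lt(abs(mean(thicknessValues(slab$res$grid)[valid, ]) - tr$t) / tr$t,
            0.02)
  ## slab slice area = a * t per row
  rows <- s@rowTable
  okRows <- rows$ok & rows$j >= 3 & rows$j <= 18
  expect_lt(max(abs(rows$sliceArea[okRows] - tr$a * tr$t)) / (tr$a * tr$t),
            0.03)
  ## shell sector: interior/exterior ratio ~ r0 / r1
  shell <- shellConstRun()
  R <- shell$phantom$truth$R
  ratio <- shell$res$summary@interiorExteriorRatio
  expect_lt(abs(ratio - (R - 1.25) / (R + 1.25)), 0.03 * (R - 1.25) / (R + 1.25) + 0.02)
  expect_gt(shell$res$summary@surfaceArea, 0)
  expect_equal(shell$res$summary@shapeIndex,
               shell$res$summary@circumference / shell$res$summary@surfaceArea)
})

test_that("scalar volumes project onto the grid by trilinear sampling", {
  run <- shellConstRun()
  grid <- run$res$grid
  vol <- run$phantom$volume
  n <- dim(labelData(vol))
  const <- array(3.25, n)
  pc <- projectScalarVolume(const, affine(vol), grid)
  expect_true(all(abs(pc - 3.25) < 1e-12, na.rm = TRUE))
  ## world-x ramp: build from voxel index -> world
  idx <- arrayInd(seq_len(prod(n)), n)
  xw <- array(hipposheet:::indexToWorld(affine(vol), idx)[, 1], n)
  px <- projectScalarVolume(xw, affine(vol), grid)
  expect_lt(max(abs(px - matrix(gridPoints(grid)[, 1], grid@N, grid@M)),
                na.rm = TRUE), 0.25)
  ## synthetic activation blob at a known angular/longitudinal position
  tr <- run$phantom$truth
  target <- tr$midSheet(pi / 3, tr$L * 0.4)
  w <- hipposheet:::indexToWorld(affine(vol), idx)
  blob <- array(exp(-rowSums((w - rep(target, each = nrow(w)))^2) / 8), n)
  pb <- projectScalarVolume(blob, affine(vol), grid)
  pk <- arrayInd(which.max(pb), dim(pb))
  uTheta <- tr$thetaFromUml(grid@uml[pk[1]])
  yPk <- grid@uap[pk[2]] * tr$L
  expect_lt(abs(uTheta - pi / 3), 2.5 * diff(tr$arc) / grid@N)
  expect_lt(abs(yPk - tr$L * 0.4), 2.5 * tr$L / grid@M)
})

test_that("voxel-based thickness oracle agrees with the slab and the mesh", {
  slab <- slabRun()
  res <- slab$res
  vo <- voxelThicknessOracle(res$mask, res$open, res$boundarySpec,
                             gridPoints(res$grid))
  valid <- slab$phantom$truth$validUml(res$grid@uml)
  vm <- matrix(vo$thickness, res$grid@N, res$grid@M)
  expect_lt(max(abs(vm[valid, ] - 3)), 0.5)     # within one voxel
  dd <- abs(vm[valid, ] - thicknessValues(res$grid)[valid, ])
  expect_lt(median(dd), 0.1 * mean(thicknessValues(res$grid)[valid, ]))
  ## invalid input: a mask with no foreground propagates a solver error
  empty <- new("BodyMask", mask = array(FALSE, c(4, 4, 4)), affine = diag(4),
               apAxis = 2L, apRange = c(1L, 4L), anteriorEnd = 2L)
  expect_error(voxelThicknessOracle(empty, res$open, res$boundarySpec,
                                    gridPoints(res$grid)))
})

test_that("grid resolution stability: doubling N, M moves the mean < 1%", {
  run <- shellConstRun()
  cs <- run$res$coords
  mid <- run$res$mid
  g2 <- computeThicknessMap(sampleMidsurfaceGrid(mid, 80L, 40L), cs)
  valid1 <- run$phantom$truth$validUml(run$res$grid@uml)
  valid2 <- run$phantom$truth$validUml(g2@uml)
  m1 <- mean(thicknessValues(run$res$grid)[valid1, ])
  m2 <- mean(thicknessValues(g2)[valid2, ])
  expect_lt(abs(m2 - m1) / m1, 0.01)
})
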