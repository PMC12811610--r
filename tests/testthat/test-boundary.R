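test_that("cutting the body surface open yields a cylinder with tagged rings", {
  run <- shellConstRun()
  o <- run$res$open
  expect_s4_class(o, "OpenSurface")
  expect_equal(surfaceEulerCharacteristic(o), 0L)
  expect_named(boundaryLoops(o), c("anterior", "posterior"))
  vox <- 1.5  # longitudinal voxel size
  caps <- run$phantom$truth$capPlanesY
  yA <- mean(vertices(o)[boundaryLoops(o)$anterior, 2])
  yP <- mean(vertices(o)[boundaryLoops(o)$posterior, 2])
  expect_lt(abs(yA - max(caps)), vox)
  expect_lt(abs(yP - min(caps)), vox)
})

test_that("flat rectangle: first Neumann mode is cos(pi x / L)", {
  L <- 2; W <- 1
  rs <- makeRectangleSurface(L = L, W = W, nx = 40L, ny = 20L)
  sp <- surfaceSpectrum(rs, anisotropy = c(0, 0), k = 3L)
  expect_lt(sp$values[1], 1e-8)
  lam <- sp$values[2]
  expect_lt(abs(lam - (pi / L)^2) / (pi / L)^2, 0.02)
  f <- sp$vectors[, 2]
  x <- vertices(rs)[, 1]
  expect_gt(abs(cor(f, cos(pi * x / L))), 0.999)
  ## zero crossings along x within one edge length of L/2
  edge <- L / 40
  cross <- which(diff(sign(f[order(x)])) != 0)
  xs <- sort(x)
  expect_true(all(abs(xs[cross] - L / 2) <= edge + 1e-9))
})

test_that("anisotropy (0,0) reproduces the cotangent Laplacian exactly", {
  run <- smallShellRun()
  o <- run$res$open
  L <- surfaceLaplacian(vertices(o), o@triangles, c(0, 0))
  oracle <- cotanLaplacianOracle(vertices(o), o@triangles)
  expect_lt(max(abs(L$K - oracle)), 1e-10)
})

test_that("eigenpairs satisfy the generalized residual and orthogonality", {
  run <- shellConstRun()
  o <- run$res$open
  f <- run$res$eigenfunction
  L <- surfaceLaplacian(vertices(o), o@triangles, f@anisotropy)
  v <- fieldValues(f)
  res <- sqrt(sum((as.numeric(L$K %*% v) - f@eigenvalue * L$mass * v)^2)) /
    sqrt(sum((L$mass * v)^2))
  expect_lt(res, 1e-8)
  ## mass-weighted orthogonality to the constant mode
  expect_lt(abs(sum(L$mass * v)) / sqrt(sum(L$mass) * sum(L$mass * v^2)),
            1e-8)
})

test_that("zero level set locks onto the high-curvature ridges", {
  run <- shellConstRun()
  o <- run$res$open
  f <- run$res$eigenfunction
  ct <- hipposheet:::faceCurvatureTensors(vertices(o), o@triangles)
  nv <- nrow(vertices(o))
  vk <- numeric(nv); vc <- numeric(nv)
  for (c0 in 1:3) {
    vk <- vk + hipposheet:::tapply2(abs(ct$k1), o@triangles[, c0], nv)
    vc <- vc + hipposheet:::tapply2(rep(1, nrow(o@triangles)),
                                    o@triangles[, c0], nv)
  }
  vk <- vk / pmax(vc, 1)
  comps <- hipposheet:::zeroSetComponents(o, fieldValues(f))
  lens <- vapply(comps, `[[`, numeric(1), "length")
  big <- which(lens >= 0.1 * max(lens))
  zs <- unique(unlist(lapply(comps[big], function(cc)
    ifelse(abs(fieldValues(f)[cc$edges[, 1]]) <=
             abs(fieldValues(f)[cc$edges[, 2]]),
           cc$edges[, 1], cc$edges[, 2]))))
  expect_gte(mean(vk[zs] >= quantile(vk, 0.75)), 0.8)
})

test_that("boundary curves sit at the ridge angles and patches split sanely", {
  run <- shellConstRun()
  o <- run$res$open
  spec <- run$res$boundarySpec
  angles <- run$phantom$truth$ridgeAngles
  thOf <- function(vs) atan2(vertices(o)[vs, 3], vertices(o)[vs, 1])
  expect_lt(abs(mean(thOf(spec@cm)) - angles[1]), 10 * pi / 180)
  expect_lt(abs(mean(thOf(spec@cl)) - angles[2]), 10 * pi / 180)
  ## patch area ratio close to the analytic inner/outer arc ratio
  aInt <- sum(hipposheet:::triangleAreas(
    vertices(o), o@triangles[spec@interiorTriangles, , drop = FALSE]))
  aExt <- sum(hipposheet:::triangleAreas(
    vertices(o), o@triangles[spec@exteriorTriangles, , drop = FALSE]))
  R <- run$phantom$truth$R; t0 <- 2.5
  expect_lt(abs(aInt / aExt - (R - t0 / 2) / (R + t0 / 2)), 0.1)
  ## every curve connects the two rings
  for (curve in list(spec@cm, spec@cl)) {
    expect_true(curve[1] %in% c(spec@anteriorRing, spec@posteriorRing))
    expect_true(curve[length(curve)] %in% c(spec@anteriorRing,
                                            spec@posteriorRing))
  }
})

test_that("swapping medial and lateral labels swaps C_m and C_l", {
  run <- shellConstRun()
  o <- run$res$open
  f <- run$res$eigenfunction
  spec <- run$res$boundarySpec
  o2 <- o
  nm <- o2@vertexData$subfieldName
  swapped <- nm
  swapped[nm %in% c("presubiculum", "subiculum")] <- "CA3"
  swapped[nm == "CA3"] <- "subiculum"
  o2@vertexData$subfieldName <- swapped
  spec2 <- deriveBoundarySpec(o2, f)
  expect_setequal(spec2@cm, spec@cl)
  expect_setequal(spec2@cl, spec@cm)
  expect_setequal(spec2@interiorTriangles, spec@interiorTriangles)
})

test_that("curve extraction is invariant to vertex reindexing", {
  run <- smallShellRun()
  o <- run$res$open
  spec <- run$res$boundarySpec
  set.seed(4)
  perm <- sample.int(nrow(vertices(o)))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  o2 <- new("OpenSurface",
            vertices = vertices(o)[perm, , drop = FALSE],
            triangles = matrix(inv[o@triangles], ncol = 3),
            vertexData = o@vertexData[perm, , drop = FALSE],
            boundaryLoops = lapply(boundaryLoops(o), function(l) inv[l]))
  f2 <- anisotropicLaplaceEigenfunction(o2, run$res$eigenfunction@anisotropy)
  spec2 <- deriveBoundarySpec(o2, f2)
  ## same curves as coordinate sets (snapping may differ at single vertices)
  cmA <- vertices(o)[spec@cm, , drop = FALSE]
  cmB <- vertices(o2)[spec2@cm, , drop = FALSE]
  d <- hipposheet:::proxy_mindist(cmB, cmA)
  expect_lt(median(d), 1e-9)
  expect_lt(max(d), 1.5)      # stray snaps stay within one edge length
})
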