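## manual coordinate system on a structured box: u = (x, y, z) exactly
boxCoordinateSystem <- function(n1 = 8L, n2 = 8L, n3 = 8L) {
  bx <- makeBoxTetMesh(1, 1, 1, n1, n2, n3)
  v <- vertices(bx)
  face <- function(d, val) which(abs(v[, d] - val) < 1e-12)
  cs <- new("CoordinateSystem", mesh = bx,
            uml = solveLaplaceFEM(bx, face(1, 0), face(1, 1),
                                  "medial_lateral"),
            uap = solveLaplaceFEM(bx, face(2, 0), face(2, 1),
                                  "anterior_posterior"),
            uie = solveLaplaceFEM(bx, face(3, 0), face(3, 1),
                                  "interior_exterior"))
  cs
}

test_that("P1 FEM reproduces linear fields exactly on the cube", {
  cs <- boxCoordinateSystem()
  v <- vertices(cs@mesh)
  expect_lt(max(abs(fieldValues(cs@uml) - v[, 1])), 1e-9)
  expect_lt(max(abs(fieldValues(cs@uap) - v[, 2])), 1e-9)
  expect_lt(max(abs(fieldValues(cs@uie) - v[, 3])), 1e-9)
})

test_that("swapping the Dirichlet sets maps u to 1 - u exactly", {
  bx <- makeBoxTetMesh(1, 1, 1, 5L, 5L, 5L)
  v <- vertices(bx)
  z0 <- which(abs(v[, 1]) < 1e-12); z1 <- which(abs(v[, 1] - 1) < 1e-12)
  u <- solveLaplaceFEM(bx, z0, z1, "medial_lateral")
  u2 <- solveLaplaceFEM(bx, z1, z0, "medial_lateral")
  expect_lt(max(abs(fieldValues(u2) - (1 - fieldValues(u)))), 1e-12)
  expect_error(solveLaplaceFEM(bx, z0, z0, "medial_lateral"), "overlapping")
  expect_error(solveLaplaceFEM(bx, integer(0), z1, "medial_lateral"),
               "empty")
})

test_that("cylindrical annulus reproduces the log-harmonic solution", {
  an <- makeAnnulusTetMesh(r0 = 5, r1 = 10, h = 4, phi = pi / 2,
                           nr = 12L, nphi = 24L, nz = 4L)
  w <- attr(an, "wallVertices")
  u <- solveLaplaceFEM(an, w$inner, w$outer, "interior_exterior")
  r <- sqrt(vertices(an)[, 1]^2 + vertices(an)[, 2]^2)
  exact <- log(r / 5) / log(2)
  expect_lt(max(abs(fieldValues(u) - exact)), 0.01)
})

test_that("harmonic residual vanishes at the free vertices", {
  cs <- boxCoordinateSystem(6L, 6L, 6L)
  K <- hipposheet:::tetStiffness(vertices(cs@mesh), tetrahedra(cs@mesh))
  u <- fieldValues(cs@uml)
  fixed <- c(cs@uml@zeroSet, cs@uml@oneSet)
  r <- as.numeric(K %*% u)
  expect_lt(max(abs(r[-fixed])), 1e-9 * max(abs(K)))
})

test_that("the shell coordinate system is well-behaved", {
  run <- shellConstRun()
  cs <- run$res$coords
  for (fld in list(cs@uml, cs@uap, cs@uie)) {
    expect_gte(min(fieldValues(fld)), 0)
    expect_lte(max(fieldValues(fld)), 1)
    expect_equal(range(fieldValues(fld)), c(0, 1))
    viol <- attr(fld, "maxPrincipleViolation")
    if (!is.null(viol)) expect_lt(viol, 1e-6)
  }
  ## orientation-consistent Jacobian in > 99% of tets
  expect_lt(hipposheet:::jacobianInvertedFraction(cs), 0.01)
  ## u_ml monotone in the angular coordinate
  v <- vertices(cs@mesh)
  th <- atan2(v[, 3], v[, 1])
  expect_gt(cor(fieldValues(cs@uml), th, method = "spearman"), 0.99)
})

test_that("level-set extraction: exact plane on the box, area on the annulus", {
  cs <- boxCoordinateSystem()
  mid <- extractIsosurface(cs, "interior_exterior", 0.5)
  expect_lt(max(abs(vertices(mid)[, 3] - 0.5)), 1e-9)
  ## interpolated coordinates ride along
  expect_lt(max(abs(vertexData(mid)$uml - vertices(mid)[, 1])), 1e-9)
  ## log-harmonic annulus: the 0.5 level sits at r* = sqrt(r0 r1)
  an <- makeAnnulusTetMesh(r0 = 5, r1 = 10, h = 4, phi = pi / 2,
                           nr = 12L, nphi = 24L, nz = 4L)
  w <- attr(an, "wallVertices")
  uie <- solveLaplaceFEM(an, w$inner, w$outer, "interior_exterior")
  dummy1 <- uie; dummy1@axis <- "medial_lateral"
  dummy2 <- uie; dummy2@axis <- "anterior_posterior"
  csA <- new("CoordinateSystem", mesh = an, uml = dummy1, uap = dummy2,
             uie = uie)
  lev <- extractIsosurface(csA, "interior_exterior", 0.5,
                           checkConnected = FALSE)
  area <- sum(hipposheet:::triangleAreas(vertices(lev), triangles(lev)))
  rstar <- sqrt(5 * 10)
  expect_lt(abs(area - rstar * pi / 2 * 4) / (rstar * pi / 2 * 4), 0.03)
  ## out-of-range level is an error
  expect_error(extractIsosurface(cs, "interior_exterior", 1.5), "range")
})
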