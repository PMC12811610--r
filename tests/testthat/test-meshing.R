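test_that("a single foreground voxel yields a closed genus-0 surface", {
  mask <- array(FALSE, c(3, 3, 3)); mask[2, 2, 2] <- TRUE
  m <- new("BodyMask", mask = mask, affine = diag(4), apAxis = 2L,
           apRange = c(1L, 3L), anteriorEnd = 2L)
  s <- extractSmoothSurface(m, smoothingIterations = 0L)
  expect_equal(surfaceEulerCharacteristic(s), 2L)
})

test_that("voxelized ball: surface area within 5% of the analytic sphere", {
  m <- ballMask(r = 10)
  s <- extractSmoothSurface(m, smoothingIterations = 5L)
  area <- sum(hipposheet:::triangleAreas(vertices(s), triangles(s)))
  expect_lt(abs(area - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_equal(surfaceEulerCharacteristic(s), 2L)
})

test_that("smoothing is mild: area and volume change < 5%", {
  m <- ballMask(r = 8)
  s0 <- extractSmoothSurface(m, smoothingIterations = 0L)
  s1 <- extractSmoothSurface(m, smoothingIterations = 10L)
  a0 <- sum(hipposheet:::triangleAreas(vertices(s0), triangles(s0)))
  a1 <- sum(hipposheet:::triangleAreas(vertices(s1), triangles(s1)))
  v0 <- hipposheet:::enclosedVolume(vertices(s0), triangles(s0))
  v1 <- hipposheet:::enclosedVolume(vertices(s1), triangles(s1))
  expect_lt(abs(a1 - a0) / a0, 0.05)
  expect_lt(abs(v1 - v0) / v0, 0.05)
  ## and no vertex moved further than one voxel diagonal
  expect_lt(max(sqrt(rowSums((vertices(s1) - vertices(s0))^2))),
            sqrt(3) + 1e-9)
})

test_that("tetrahedralize fills the unit cube exactly and a ball within 2%", {
  cube <- unitCubeSurface()
  tm <- tetrahedralize(cube)
  expect_equal(sum(tetVolumes(tm)), 1.0, tolerance = 1e-6)
  expect_gt(min(tetVolumes(tm)), 0)
  m <- ballMask(r = 8)
  s <- extractSmoothSurface(m, smoothingIterations = 5L)
  tmb <- tetrahedralize(s)
  encl <- hipposheet:::enclosedVolume(vertices(s), triangles(s))
  expect_lt(abs(sum(tetVolumes(tmb)) - encl) / encl, 0.02)
  expect_gt(min(tetVolumes(tmb)), 0)
})

test_that("slab phantom: mesh volume within 3% of the analytic slab", {
  run <- slabRun()
  vol <- sum(tetVolumes(run$res$mesh))
  truth <- run$phantom$truth$volume
  expect_lt(abs(vol - truth) / truth, 0.03)
})

test_that("label transfer: containment, tie-break, and phantom agreement", {
  dial <- labelDialectTable("phantom")
  arr <- array(0L, c(5, 5, 5))
  arr[2, 3, 3] <- dial[["CA1"]]       # code 3
  arr[4, 3, 3] <- dial[["subiculum"]] # code 2
  vol <- new("LabelVolume", data = arr, affine = diag(4),
             dialect = "phantom", labels = dial)
  verts <- rbind(c(1, 2, 2),          # center of the CA1 voxel
                 c(2, 2, 2))          # equidistant between both codes
  mesh <- new("TetrahedralMesh", vertices = verts,
              tets = matrix(integer(0), 0, 4),
              boundaryTriangles = matrix(integer(0), 0, 3),
              vertexData = data.frame(subfield = c(NA_integer_, NA),
                                      cap = c(NA_character_, NA)))
  out <- transferLabels(mesh, vol)
  expect_equal(out@vertexData$subfield[1], dial[["CA1"]])
  ## tie: lowest code (subiculum = 2) wins
  expect_equal(out@vertexData$subfield[2], dial[["subiculum"]])
  ## phantom: vertex labels match the analytic angular partition
  run <- shellConstRun()
  surf <- run$res$surface
  th <- atan2(vertices(surf)[, 3], vertices(surf)[, 1])
  part <- run$phantom$truth$partition
  band <- findInterval(th, c(part$thetaLo, part$thetaHi[5]),
                       all.inside = TRUE)
  expLab <- labelDialectTable("phantom")[part$name[band]]
  agree <- mean(vertexData(surf)$subfield == expLab)
  expect_gte(agree, 0.95)
})

test_that("surfaces and tet meshes serialize losslessly (PLY, VTK, FS)", {
  m <- ballMask(r = 5)
  s <- extractSmoothSurface(m, smoothingIterations = 3L)
  f <- tempfile(fileext = ".ply")
  writeSurfacePLY(s, f, scalars = list(val = seq_len(nrow(vertices(s))) / 7))
  back <- readSurfacePLY(f)
  expect_identical(back@triangles, s@triangles)
  expect_identical(back@vertices, s@vertices)
  expect_identical(back@vertexData$val, seq_len(nrow(vertices(s))) / 7)
  vt <- tempfile(fileext = ".vtk")
  writeTetVTK(tetrahedralize(s), vt)
  expect_gt(file.info(vt)$size, 1000)
  fs <- tempfile()
  writeSurfaceFS(s, fs)
  con <- file(fs, "rb")
  magic <- readBin(con, integer(), 3, size = 1, signed = FALSE)
  close(con)
  expect_equal(magic, c(255L, 255L, 254L))
})
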