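test_that("NIfTI label volumes round-trip through write/load", {
  ph <- makeCurvedShellPhantom(phantomSpec(L = 12, capDepth = 3))
  f <- tempfile(fileext = ".nii.gz")
  writeLabelVolume(ph$volume, f)
  back <- loadLabelVolume(f, "phantom")
  expect_identical(back@data, ph$volume@data)
  expect_equal(back@affine, ph$volume@affine, tolerance = 1e-6)
})

test_that("background-only volumes load without error", {
  vol <- new("LabelVolume", data = array(0L, c(2, 2, 2)), affine = diag(4),
             dialect = "phantom", labels = labelDialectTable("phantom"))
  f <- tempfile(fileext = ".nii")
  writeLabelVolume(vol, f)
  back <- loadLabelVolume(f, "phantom")
  expect_true(all(back@data == 0L))
})

test_that("codes absent from the dialect are kept but reported", {
  arr <- array(0L, c(4, 4, 4)); arr[2, 2, 2] <- 999L; arr[3, 3, 3] <- 3L
  vol <- new("LabelVolume", data = arr, affine = diag(4),
             dialect = "phantom", labels = labelDialectTable("phantom"))
  f <- tempfile(fileext = ".nii")
  writeLabelVolume(vol, f)
  expect_warning(back <- loadLabelVolume(f, "phantom"), "999")
  expect_equal(sum(back@data == 999L), 1L)
})

test_that("MGZ volumes are read with data and scaled affine intact", {
  arr <- array(sample.int(5L, 60, replace = TRUE) - 1L, c(3, 4, 5))
  f <- tempfile(fileext = ".mgz")
  writeMGZFixture(arr, c(0.5, 0.5, 1.5), f)
  vol <- loadLabelVolume(f, "phantom")
  expect_identical(vol@data, arr)
  expect_equal(vol@affine, diag(c(0.5, 0.5, 1.5, 1)), tolerance = 1e-6)
})

test_that("non-integral volumes and unknown dialects are rejected", {
  img <- RNifti::asNifti(array(runif(8), c(2, 2, 2)))
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  expect_error(loadLabelVolume(f, "phantom"), "non-integral")
  expect_error(labelDialectTable("nosuchdialect"), "unknown dialect")
})

test_that("prepare_body_mask crops to head/tail labels and excludes CA4/DG", {
  ph <- makeCurvedShellPhantom(phantomSpec())
  m <- prepareBodyMask(ph$volume)
  ## body slices = exactly those between the head and tail labels
  lab <- ph$volume@data
  dial <- labelDialectTable("phantom")
  bodySlices <- which(apply(
    array(lab %in% dial[c("presubiculum", "subiculum", "CA1", "CA2", "CA3")],
          dim(lab)), m@apAxis, any))
  expect_equal(m@apRange, range(bodySlices))
  ## CA4/DG-only volume has no body
  arr <- array(0L, c(6, 6, 6)); arr[3:4, 3:4, 3:4] <- dial[["CA4"]]
  bad <- new("LabelVolume", data = arr, affine = diag(4),
             dialect = "phantom", labels = dial)
  expect_error(prepareBodyMask(bad), "body subfield")
})

test_that("molecular-layer voxels are reassigned without changing the count", {
  dial <- labelDialectTable("phantom")
  arr <- array(0L, c(10, 8, 8))
  arr[2:4, 2:7, 3:6] <- dial[["CA1"]]
  arr[5:7, 2:7, 3:6] <- dial[["CA2"]]
  arr[8, 2:7, 3:6] <- dial[["molecular_layer"]]
  vol <- new("LabelVolume", data = arr, affine = diag(4),
             dialect = "phantom", labels = dial)
  m <- prepareBodyMask(vol, closureIterations = 0L)
  before <- sum(arr %in% dial[c("CA1", "CA2", "molecular_layer")])
  expect_equal(sum(m@mask), before)
  ## ML voxels adjacent to CA2 become part of the mask (nearest subfield)
  expect_true(all(m@mask[8, 2:7, 3:6]))
})

test_that("closure fills single-voxel holes (morphology oracle)", {
  dial <- labelDialectTable("phantom")
  arr <- array(0L, c(12, 12, 8))
  arr[2:11, 2:11, 2:6] <- dial[["CA1"]]
  arr[2:4, 2:11, 2:6] <- dial[["CA2"]]      # medial band, all slices
  solid <- arr > 0
  arr[7, 6, 4] <- 0L                        # interior hole
  vol <- new("LabelVolume", data = arr, affine = diag(4),
             dialect = "phantom", labels = dial)
  m <- prepareBodyMask(vol, closureIterations = 1L)
  ## oracle: closure of the holey mask equals the solid block here
  expect_true(m@mask[7, 6, 4])
  expect_identical(m@mask, solid)
})

test_that("prepare_body_mask is idempotent on its own output", {
  ph <- makeCurvedShellPhantom(phantomSpec(L = 12, capDepth = 3))
  m1 <- prepareBodyMask(ph$volume)
  ## rebuild a label volume from the mask (labels from nearest subfield)
  dial <- labelDialectTable("phantom")
  lab2 <- ph$volume@data
  lab2[!m1@mask & !(lab2 %in% dial[c("head", "tail")])] <- 0L
  nlm <- hipposheet:::nearestLabelMap(ph$volume@data,
                                      dial[c("presubiculum", "subiculum",
                                             "CA1", "CA2", "CA3")],
                                      c(0.5, 1.5, 0.5))
  fill <- m1@mask & lab2 == 0L
  lab2[fill] <- nlm[fill]
  vol2 <- new("LabelVolume", data = lab2, affine = ph$volume@affine,
              dialect = "phantom", labels = dial)
  m2 <- prepareBodyMask(vol2)
  expect_identical(m2@mask, m1@mask)
  expect_identical(m2@apRange, m1@apRange)
})

test_that("topology report flags disconnected and cavitated masks", {
  solid <- array(FALSE, c(10, 10, 10)); solid[2:8, 2:8, 2:8] <- TRUE
  mk <- function(a) new("BodyMask", mask = a, affine = diag(4), apAxis = 2L,
                        apRange = c(1L, 10L), anteriorEnd = 2L)
  tp <- checkMaskTopology(mk(solid))
  expect_equal(tp$nComponents, 1L)
  expect_equal(tp$nBackgroundComponents, 1L)
  expect_equal(tp$eulerBoundary, 2L)
  expect_false(tp$fatal)
  two <- solid; two[5, , ] <- FALSE       # split into two slabs
  tp2 <- checkMaskTopology(mk(two))
  expect_equal(tp2$nComponents, 2L)
  expect_true(tp2$fatal)
  cav <- solid; cav[5, 5, 5] <- FALSE     # interior cavity
  tp3 <- checkMaskTopology(mk(cav))
  expect_equal(tp3$nBackgroundComponents, 2L)
  expect_true(tp3$fatal)
})
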