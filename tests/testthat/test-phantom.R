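test_that("slab phantom digitizes the analytic volume exactly", {
  ph <- makeSlabPhantom(a = 20, b = 30, t = 3, voxel = c(0.5, 0.5, 0.5))
  nBody <- sum(ph$volume@data %in% 1:5)
  expect_equal(nBody * 0.125, 20 * 30 * 3, tolerance = 0)
  expect_error(makeSlabPhantom(t = 0.8, voxel = c(0.5, 0.5, 0.5)),
               "not resolvable")
})

test_that("shell phantom respects resolvability and self-intersection guards", {
  expect_error(makeCurvedShellPhantom(
    phantomSpec(thicknessFn = function(th, y) rep(0.9, length(th)))),
    "not resolvable")
  expect_error(makeCurvedShellPhantom(
    phantomSpec(R = 3, thicknessFn = function(th, y) rep(2.6, length(th)),
                arc = c(0, 0.6))),
    "self-intersects")
})

test_that("same seed gives byte-identical phantoms and cohorts", {
  a <- makeCurvedShellPhantom(phantomSpec(L = 10, capDepth = 3, seed = 7L))
  b <- makeCurvedShellPhantom(phantomSpec(L = 10, capDepth = 3, seed = 7L))
  expect_identical(a$volume@data, b$volume@data)
  expect_identical(a$volume@affine, b$volume@affine)
  c1 <- simulateCohort(nPerGroup = c(CU = 5, MCI = 5), seed = 42L)
  c2 <- simulateCohort(nPerGroup = c(CU = 5, MCI = 5), seed = 42L)
  expect_identical(c1, c2)
})

test_that("phantom RNG use does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(makeCurvedShellPhantom(
    phantomSpec(L = 10, capDepth = 3, seed = 5L)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("voxelization error of the shell walls shrinks ~linearly with voxel size", {
  wallError <- function(h) {
    ph <- makeCurvedShellPhantom(
      phantomSpec(L = 9, capDepth = 3, voxel = c(h, 1.5, h), ridgeAmp = 0,
                  seed = 3L))
    lab <- ph$volume@data
    mask <- array(lab %in% 1:5, dim(lab))
    bg <- !mask
    touch <- mask & (hipposheet:::shiftArray(bg, c(1, 0, 0), TRUE) |
                       hipposheet:::shiftArray(bg, c(-1, 0, 0), TRUE) |
                       hipposheet:::shiftArray(bg, c(0, 0, 1), TRUE) |
                       hipposheet:::shiftArray(bg, c(0, 0, -1), TRUE))
    idx <- which(touch)
    w <- hipposheet:::indexToWorld(ph$volume@affine, arrayInd(idx, dim(lab)))
    th <- atan2(w[, 3], w[, 1])
    keep <- w[, 2] > 2 & w[, 2] < 7 & th > 0.4 & th < pi - 0.4
    r <- sqrt(w[keep, 1]^2 + w[keep, 3]^2)
    mean(abs(abs(r - 15) - 2.5 / 2))
  }
  e1 <- wallError(0.5)
  e2 <- wallError(0.25)
  expect_lt(e2, e1 / 1.4)      # order-1 convergence (halving ~halves it)
})

test_that("cohort simulation encodes the requested group structure", {
  co <- simulateCohort(nPerGroup = c(CU = 6, MCI = 6), delta = 0.5,
                       patch = list(i = c(10, 20), j = c(5, 15)),
                       sigma = 0.01, shiftRange = 0L, seed = 9L)
  expect_length(co, 12L)
  grps <- vapply(co, `[[`, character(1), "group")
  expect_equal(sum(grps == "MCI"), 6L)
  cu <- Reduce(`+`, lapply(co[grps == "CU"], `[[`, "thickness")) / 6
  mci <- Reduce(`+`, lapply(co[grps == "MCI"], `[[`, "thickness")) / 6
  dd <- cu - mci
  expect_gt(mean(dd[10:20, 5:15]), 0.4)          # thinning in the patch
  expect_lt(mean(abs(dd[25:40, ])), 0.15)        # little effect outside
  expect_error(simulateCohort(patch = list(i = c(30, 45), j = c(1, 5))),
               "patch")
})
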