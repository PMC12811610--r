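test_that("identical curvature profiles align with zero shift", {
  prof <- 0.03 + 0.4 * exp(-(seq_len(40) - 8)^2 / 8) +
    0.3 * exp(-(seq_len(40) - 33)^2 / 10)
  subj <- list(curvature = matrix(prof, 40, 20),
               thickness = matrix(2.5, 40, 20))
  al <- alignThicknessMaps(list(subj, subj, subj))
  expect_equal(al$shifts, c(0, 0, 0))
})

test_that("a 2-cell translation is recovered and undone", {
  base <- simulateCohort(nPerGroup = c(CU = 1), delta = 0, sigma = 1e-4,
                         shiftRange = 0L, seed = 2L)[[1]]
  shifted <- base
  shifted$curvature <- hipposheet:::shiftMapRows(base$curvature, 2)
  shifted$thickness <- hipposheet:::shiftMapRows(base$thickness, 2)
  al <- alignThicknessMaps(list(base, shifted),
                           reference = rowMeans(base$curvature))
  expect_equal(al$shifts[2], 2, tolerance = 0.05)
  interior <- 4:37
  expect_lt(max(abs(al$subjects[[2]]$thickness[interior, ] -
                      base$thickness[interior, ])), 0.05)
})

test_that("noisy cohort shifts are recovered to < 0.5 cells MAE", {
  co <- simulateCohort(nPerGroup = c(CU = 30), delta = 0, sigma = 0,
                       shiftRange = 3L, seed = 5L)
  ref <- rowMeans(simulateCohort(nPerGroup = c(CU = 1), delta = 0,
                                 sigma = 1e-6, shiftRange = 0L,
                                 seed = 999L)[[1]]$curvature)
  al <- alignThicknessMaps(co, reference = ref)
  err <- al$shifts - vapply(co, `[[`, numeric(1), "shift")
  expect_lt(mean(abs(err)), 0.5)
  ## flat profile: zero shift, not an error
  flat <- list(curvature = matrix(0.01, 40, 20),
               thickness = matrix(2, 40, 20))
  al2 <- alignThicknessMaps(list(flat), reference = ref)
  expect_equal(al2$shifts, 0)
})

test_that("aligning an unshifted cohort leaves the statistics unchanged", {
  co <- simulateCohort(nPerGroup = c(CU = 10, MCI = 10), delta = 0.4,
                       sigma = 0.2, shiftRange = 0L, seed = 31L)
  des <- data.frame(group = vapply(co, `[[`, character(1), "group"),
                    age = vapply(co, `[[`, numeric(1), "age"),
                    sex = vapply(co, `[[`, numeric(1), "sex"))
  raw <- lapply(co, `[[`, "thickness")
  al <- alignThicknessMaps(co)
  expect_lt(max(abs(al$shifts)), 0.3)
  r1 <- vertexwiseGLM(raw, des)
  r2 <- vertexwiseGLM(lapply(al$subjects, `[[`, "thickness"), des)
  expect_gt(cor(as.numeric(r1@t), as.numeric(r2@t)), 0.98)
})

test_that("vertexwise GLM: null gives t = 0, and matches the pooled t test", {
  maps <- lapply(1:8, function(i) matrix(3.0, 10, 5))
  des <- data.frame(group = rep(c("A", "B"), each = 4),
                    age = rnorm(8), sex = rep(0:1, 4))
  r <- vertexwiseGLM(maps, des)
  expect_true(all(r@t == 0))
  expect_true(all(r@p == 1))
  ## two-sample oracle without covariates
  set.seed(7)
  maps2 <- lapply(1:8, function(i)
    matrix(rnorm(50, mean = 3 + 0.3 * (i > 4)), 10, 5))
  r2 <- vertexwiseGLM(maps2, des[, "group", drop = FALSE],
                      covariates = character(0))
  for (k in c(1L, 17L, 50L)) {
    i <- ((k - 1L) %% 10) + 1L; j <- ((k - 1L) %/% 10) + 1L
    a <- vapply(maps2[1:4], function(m) m[i, j], numeric(1))
    b <- vapply(maps2[5:8], function(m) m[i, j], numeric(1))
    tt <- t.test(b, a, var.equal = TRUE)
    expect_equal(r2@t[i, j], unname(tt$statistic), tolerance = 1e-10)
  }
  ## GLM coefficients equal the normal-equations solution
  X <- cbind(1, rep(0:1, each = 4))
  y <- vapply(maps2, function(m) m[3, 2], numeric(1))
  beta <- solve(crossprod(X), crossprod(X, y))
  fitIntercept <- mean(y[1:4])
  expect_equal(beta[1], fitIntercept, tolerance = 1e-8)
  ## rank-deficient design names the collinear column
  des3 <- data.frame(group = rep(c("A", "B"), each = 4),
                     age = rep(c(0, 1), each = 4))
  expect_error(vertexwiseGLM(maps2, des3, covariates = "age"),
               "collinear.*age")
})

test_that("FDR2 matches the brute-force step-up oracle exactly", {
  set.seed(11)
  p <- matrix(runif(200), 20, 10)
  res <- fdr2Correct(list(p), q = 0.05)
  expect_equal(as.numeric(res$pAdjusted[[1]]), bruteForceBH(as.numeric(p)),
               tolerance = 1e-15)
  ## joint across two hemispheres equals BH on the pooled vector
  p2 <- matrix(runif(200), 20, 10)
  res2 <- fdr2Correct(list(p, p2), q = 0.05)
  pooled <- bruteForceBH(c(as.numeric(p), as.numeric(p2)))
  expect_equal(c(as.numeric(res2$pAdjusted[[1]]),
                 as.numeric(res2$pAdjusted[[2]])), pooled,
               tolerance = 1e-15)
  ## edge cases
  allOne <- fdr2Correct(matrix(1, 5, 5), q = 0.05)
  expect_false(any(allOne$mask[[1]]))
  single <- fdr2Correct(matrix(0.04, 1, 1), q = 0.05)
  expect_equal(single$pAdjusted[[1]][1, 1], 0.04)
  expect_true(single$mask[[1]][1, 1])
  expect_error(fdr2Correct(matrix(1.5, 2, 2)), "p values")
})

test_that("adjusted p never undercuts raw p and peaks are significant maxima", {
  set.seed(3)
  maps <- lapply(1:24, function(i)
    matrix(rnorm(200, mean = 3 - 0.3 * (i > 12) * rep(c(0, 1), each = 100)),
           20, 10))
  des <- data.frame(group = rep(c("A", "B"), each = 12))
  r <- vertexwiseGLM(maps, des, covariates = character(0))
  expect_true(all(r@pAdjusted >= r@p - 1e-12))
  if (any(r@significant))
    expect_true(r@significant[r@peak[1], r@peak[2]])
})

test_that("incremental classification behaves on signal, redundancy, separation", {
  set.seed(21)
  n <- 80; grp <- rep(0:1, each = n / 2)
  vol <- 10 - 0.6 * grp + rnorm(n)
  thk <- 3 - 0.5 * grp + rnorm(n, 0, 0.4)
  ic <- incrementalClassification(vol, thk, grp)
  expect_gt(ic$auc1, ic$auc0)
  expect_lt(ic$lrP, 0.05)
  expect_false(ic$separationFlag)
  expect_true(ic$auc0CI[1] <= ic$auc0 && ic$auc0 <= ic$auc0CI[2])
  ## redundant predictor: LR ~ 0
  ic2 <- incrementalClassification(vol, vol, grp)
  expect_lt(ic2$lrStatistic, 1e-6)
  ## perfect separation flagged, fallback still returns finite results
  volSep <- c(rep(1, 20), rep(5, 20))
  grpSep <- rep(0:1, each = 20)
  ic3 <- incrementalClassification(volSep, rnorm(40), grpSep)
  expect_true(ic3$separationFlag)
  expect_true(is.finite(ic3$lrP))
  expect_error(incrementalClassification(vol[1:10], thk[1:10], grp[1:10]),
               "at least 20")
})
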