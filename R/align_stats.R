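## align_stats: curvature-based inter-subject alignment along the
## medial/lateral axis, grid-point-wise linear models with joint FDR
## control, and incremental logistic classification.

#' Curvature-based alignment of thickness maps
#'
#' Each subject's curvature profile (the N-vector of curvature averaged
#' across the anterior/posterior dimension) is shifted along the
#' medial/lateral axis to maximize its Pearson correlation with a reference
#' profile, searching fractional shifts in `[-sMax, sMax]` (step 0.05
#' cells, linear interpolation with edge extension). The recovered shift is
#' then applied to every row of the subject's thickness map. With
#' `reference = "mean"` the reference is the cross-subject mean profile and
#' the procedure iterates twice (re-estimating the mean from aligned
#' profiles).
#'
#' @param subjects list of subjects, each a list with `curvature` and
#'   `thickness` (N x M matrices, as from [simulateCohort()] or grid
#'   exports).
#' @param reference "mean" or a numeric length-N profile.
#' @param sMax maximal absolute shift in grid cells.
#' @return list with `subjects` (thickness replaced by the aligned map,
#'   original kept as `thicknessRaw`), `shifts`, and `reference`.
#' @export
alignThicknessMaps <- function(subjects, reference = "mean",
                               sMax = hipposheetDefaults()$sMax) {
  profiles <- vapply(subjects, function(s) rowMeans(s$curvature),
                     numeric(nrow(subjects[[1]]$curvature)))
  N <- nrow(profiles)
  getShift <- function(prof, ref) {
    if (stats::sd(prof) < 1e-12) return(structure(0, flagged = TRUE))
    ss <- seq(-sMax, sMax, by = 0.05)
    co <- vapply(ss, function(s) {
      ## undo a displacement of +s cells and correlate with the reference
      ## over the non-extrapolated overlap
      shifted <- stats::approx(seq_len(N), prof, xout = seq_len(N) + s,
                               rule = 1)$y
      ok <- !is.na(shifted)
      if (sum(ok) < 0.6 * N || stats::sd(shifted[ok]) < 1e-12) -Inf
      else stats::cor(shifted[ok], ref[ok])
    }, numeric(1))
    ss[which.max(co)]
  }
  runPass <- function(ref) vapply(seq_along(subjects), function(i)
    as.numeric(getShift(profiles[, i], ref)), numeric(1))
  if (identical(reference, "mean")) {
    ref <- rowMeans(profiles)
    shifts <- runPass(ref)
    aligned <- vapply(seq_along(subjects), function(i)
      stats::approx(seq_len(N), profiles[, i], xout = seq_len(N) + shifts[i],
                    rule = 2)$y, numeric(N))
    ref <- rowMeans(aligned)
    shifts <- runPass(ref)
  } else {
    ref <- reference
    shifts <- runPass(ref)
  }
  out <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    s$thicknessRaw <- s$thickness
    s$thickness <- shiftMapRows(s$thickness, -shifts[i])
    s$shiftApplied <- shifts[i]
    s
  })
  list(subjects = out, shifts = shifts, reference = ref)
}

#' Grid-point-wise general linear model
#'
#' Ordinary-least-squares fit at every grid point of thickness on the
#' design (group contrast of interest plus covariates), with the two-sided
#' t test for the contrast. All points are fit simultaneously through the
#' normal equations.
#'
#' @param maps list of N x M matrices (one per subject, aligned).
#' @param design data.frame with a `group` factor (2 levels; the second
#'   level is the effect direction) and optional numeric covariates (e.g.
#'   `age`, `sex`).
#' @param covariates character vector of design columns to adjust for.
#' @param q FDR level for the significance mask (joint across the maps
#'   passed to [fdr2Correct()]; here per-map for convenience).
#' @return a [GridStatResult-class].
#' @export
vertexwiseGLM <- function(maps, design, covariates = intersect(
                            c("age", "sex"), names(design)), q = 0.05) {
  n <- length(maps)
  if (n != nrow(design))
    hsError("align_stats", "number of maps (%d) and design rows (%d) differ",
            n, nrow(design))
  g <- factor(design$group)
  if (nlevels(g) != 2L)
    hsError("align_stats", "group must have exactly 2 levels")
  if (min(table(g)) < 2L)
    hsError("align_stats", "need at least 2 subjects per group")
  X <- cbind(1, as.numeric(g) - 1)
  colnames(X) <- c("(Intercept)", "group")
  for (cv in covariates) X <- cbind(X, as.numeric(design[[cv]]))
  colnames(X)[-(1:2)] <- covariates
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    hsError("align_stats", "rank-deficient design: collinear column(s) %s",
            paste(drop, collapse = ", "))
  }
  N <- nrow(maps[[1]]); M <- ncol(maps[[1]])
  Y <- t(vapply(maps, as.numeric, numeric(N * M)))   # n x (N*M)
  XtXinv <- chol2inv(qr.R(qrX))
  B <- XtXinv %*% crossprod(X, Y)                     # p x (N*M)
  res <- Y - X %*% B
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  cvec <- as.numeric(colnames(X) == "group")
  se <- sqrt(pmax(sigma2 * as.numeric(t(cvec) %*% XtXinv %*% cvec), 1e-300))
  tstat <- as.numeric(cvec %*% B) / se
  tstat[sigma2 < 1e-24] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  adj <- fdr2Correct(list(matrix(p, N, M)), q = q)
  tm <- matrix(tstat, N, M)
  sig <- adj$mask[[1]]
  peakPool <- if (any(sig)) which(sig) else seq_len(N * M)
  pk <- peakPool[which.max(abs(tm[peakPool]))]
  new("GridStatResult", t = tm, p = matrix(p, N, M),
      pAdjusted = adj$pAdjusted[[1]], significant = sig,
      peak = c(((pk - 1L) %% N) + 1L, ((pk - 1L) %/% N) + 1L),
      df = df)
}

#' Joint false-discovery-rate correction across hemispheres
#'
#' Benjamini-Hochberg step-up adjustment applied jointly across all grid
#' points of the supplied maps (typically the left and right hemisphere of
#' one contrast -- the joint-two-map convention; pass a single map for
#' per-map correction).
#'
#' @param pMaps list of matrices of raw p values (or a single matrix).
#' @param q target FDR level.
#' @return list with `pAdjusted` (list of matrices), `mask` (adjusted p <=
#'   q), and `q`.
#' @export
fdr2Correct <- function(pMaps, q = 0.05) {
  if (is.matrix(pMaps)) pMaps <- list(pMaps)
  if (any(vapply(pMaps, function(m) any(m < 0 | m > 1, na.rm = TRUE),
                 logical(1))))
    hsError("align_stats", "p values outside [0, 1]")
  flat <- unlist(lapply(pMaps, as.numeric))
  adj <- stats::p.adjust(flat, method = "BH")
  sizes <- vapply(pMaps, length, integer(1))
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  pAdj <- lapply(seq_along(pMaps), function(i)
    matrix(adj[starts[i]:ends[i]], nrow(pMaps[[i]]), ncol(pMaps[[i]])))
  list(pAdjusted = pAdj, mask = lapply(pAdj, function(m) m <= q), q = q)
}

## Minimal ridge-penalized logistic IRLS, used only as the
## perfect-separation fallback.
ridgeLogistic <- function(X, y, lambda = 1e-4, iter = 100L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + diag(lambda, ncol(X))
    step <- solve(H, crossprod(X, y - mu) - lambda * beta)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- as.numeric(X %*% beta)
  list(coef = beta, fitted = 1 / (1 + exp(-eta)),
       logLik = sum(y * eta - log1p(exp(eta))))
}

#' Incremental classification value of thickness beyond volume
#'
#' Fits logistic models M0 (group ~ volume) and M1 (group ~ volume + mean
#' thickness), reports in-sample AUCs with bootstrap confidence intervals,
#' and the likelihood-ratio test of the thickness term (2 * (l1 - l0) ~
#' chi-squared with 1 df). Perfect separation triggers a ridge-penalized
#' fallback and is flagged.
#'
#' @param volume,thickness,group per-subject predictor vectors and binary
#'   group labels (factor or 0/1).
#' @param nBoot bootstrap replicates for the AUC confidence intervals.
#' @param seed RNG seed for the bootstrap.
#' @return list with `auc0`, `auc1`, their CIs, `lrStatistic`, `lrP`,
#'   `separationFlag`.
#' @export
incrementalClassification <- function(volume, thickness, group,
                                      nBoot = 200L, seed = 1L) {
  y <- if (is.factor(group)) as.numeric(group) - 1 else as.numeric(group)
  if (!all(y %in% c(0, 1)))
    hsError("align_stats", "group must be binary")
  if (length(y) < 20L)
    hsError("align_stats", "need at least 20 subjects")
  d <- data.frame(y = y, volume = as.numeric(volume),
                  thickness = as.numeric(thickness))
  sep <- FALSE
  fit <- function(formula, X) {
    g <- withCallingHandlers(
      stats::glm(formula, data = d, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    pf <- stats::fitted(g)
    ## separation also shows up as fitted probabilities pinned at 0/1
    if (!g$converged || any(pf > 1 - 1e-6) || any(pf < 1e-6)) sep <<- TRUE
    if (sep) {
      r <- ridgeLogistic(X, y)
      list(fitted = r$fitted, logLik = r$logLik)
    } else list(fitted = pf, logLik = as.numeric(stats::logLik(g)))
  }
  X0 <- cbind(1, d$volume)
  X1 <- cbind(1, d$volume, d$thickness)
  m0 <- fit(y ~ volume, X0)
  m1 <- fit(y ~ volume + thickness, X1)
  lr <- max(0, 2 * (m1$logLik - m0$logLik))
  lrP <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  aucOf <- function(resp, pred) {
    as.numeric(pROC::auc(pROC::roc(resp, pred, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }
  auc0 <- aucOf(y, m0$fitted); auc1 <- aucOf(y, m1$fitted)
  ci <- if (nBoot > 0L) withSeed(seed, function() {
    reps <- vapply(seq_len(nBoot), function(b) {
      i <- sample.int(length(y), replace = TRUE)
      if (length(unique(y[i])) < 2L) return(c(NA_real_, NA_real_))
      c(aucOf(y[i], m0$fitted[i]), aucOf(y[i], m1$fitted[i]))
    }, numeric(2))
    apply(reps, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }) else matrix(NA_real_, 2, 2)
  list(auc0 = auc0, auc1 = auc1,
       auc0CI = ci[, 1], auc1CI = ci[, 2],
       lrStatistic = lr, lrP = lrP, separationFlag = sep)
}
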