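## phantom: synthetic label volumes with analytic ground truth, and
## synthetic cohorts for statistical testing.

## Run code under a fixed RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Specification of the curved-shell phantom
#'
#' The phantom emulates the segmentation inputs the pipeline is designed
#' for: an anisotropic-voxel label volume of a curved sheet (a cylindrical
#' shell sector around the longitudinal world y axis) with head/tail caps
#' and pseudo-subfield labels, with known thickness, curvature and mid-sheet
#' geometry. Longitudinal ridges at the two angular edges of the sheet are
#' realised by a local thickness taper, which sharpens the rim and raises
#' local surface curvature there (the attractors for boundary detection).
#'
#' @param R mid-sheet radius (mm).
#' @param arc angular span `c(theta0, theta1)` in radians (open sheet).
#' @param L body length along y (mm).
#' @param thicknessFn function(theta, y) -> thickness in mm (before the
#'   ridge taper).
#' @param voxel voxel sizes in mm; the default c(0.5, 1.5, 0.5) mirrors
#'   high-resolution T2 hippocampal acquisitions (0.5 mm in-plane, 1.5 mm
#'   thick slices along the longitudinal y axis).
#' @param capDepth length of the head/tail caps (mm).
#' @param ridgeAmp,ridgeWidth relative thickness taper depth and angular
#'   width (radians) of the edge ridges.
#' @param seed integer; controls sub-voxel placement jitter of the
#'   voxelization grid.
#' @return a list of class `PhantomSpec`.
#' @export
phantomSpec <- function(R = 15, arc = c(0, pi), L = 30,
                        thicknessFn = function(theta, y) rep(2.5, length(theta)),
                        voxel = c(0.5, 1.5, 0.5), capDepth = 4.5,
                        ridgeAmp = 0.5, ridgeWidth = 6 * pi / 180,
                        seed = 1L) {
  stopifnot(R > 0, L > 0, diff(arc) > 0, diff(arc) < 2 * pi,
            all(voxel > 0), capDepth > 0, ridgeAmp >= 0, ridgeAmp < 1)
  spec <- list(R = R, arc = arc, L = L, thicknessFn = thicknessFn,
               voxel = voxel, capDepth = capDepth, ridgeAmp = ridgeAmp,
               ridgeWidth = ridgeWidth, seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  spec
}

## Effective local thickness including the ridge taper at the sheet edges.
phantomLocalThickness <- function(spec, theta, y) {
  t0 <- spec$thicknessFn(theta, y)
  taper <- spec$ridgeAmp *
    (exp(-(theta - spec$arc[1])^2 / (2 * spec$ridgeWidth^2)) +
     exp(-(theta - spec$arc[2])^2 / (2 * spec$ridgeWidth^2)))
  t0 * (1 - taper)
}

## Pseudo-subfield partition: five equal angular bands from the medial
## (presubiculum) to the lateral (CA3) edge.
phantomPartition <- function(arc) {
  breaks <- seq(arc[1], arc[2], length.out = 6L)
  data.frame(name = bodySubfieldNames,
             thetaLo = breaks[1:5], thetaHi = breaks[2:6])
}

#' Generate the curved-shell phantom
#'
#' Voxelizes the sheet \{(r, theta, y): |r - R| <= t(theta, y)/2,
#' theta in arc, y in [0, L]\} on an anisotropic voxel grid, adds head and
#' tail caps (solid continuations of the sheet labeled `head`/`tail`), and
#' attaches analytic ground truth: the mid-sheet, the local thickness field
#' (including the ridge taper), the mean curvature 1/(2R) away from the
#' ridges, the ridge angles, and the mapping between intrinsic coordinates
#' and (theta, y).
#'
#' @param spec a [phantomSpec()].
#' @return list with `volume` (a [LabelVolume-class]) and `truth` (a list).
#' @export
makeCurvedShellPhantom <- function(spec = phantomSpec()) {
  maxInPlane <- max(spec$voxel[c(1, 3)])   # thickness lives in the x-z plane
  thProbe <- seq(spec$arc[1], spec$arc[2], length.out = 201)
  tBase <- spec$thicknessFn(thProbe, rep(spec$L / 2, 201))
  tProbe <- phantomLocalThickness(spec, thProbe, rep(spec$L / 2, 201))
  if (min(tBase) <= 2 * maxInPlane)
    hsError("phantom", "sheet thickness (min %.2f mm) not resolvable at %.2f mm in-plane voxels",
            min(tBase), maxInPlane)
  if (min(tProbe) <= maxInPlane)
    hsError("phantom", "ridge taper narrows the rim below one in-plane voxel")
  if (max(tProbe) / 2 >= spec$R * sin(diff(spec$arc) / 2))
    hsError("phantom", "inner wall self-intersects (t/2 >= R * sin margin)")

  jitter <- withSeed(spec$seed, function() (stats::runif(3) - 0.5) * 0.5) *
    spec$voxel
  tMax <- max(tProbe)
  ## world bounding box of sheet + caps, with a 2-voxel background margin
  th <- seq(spec$arc[1], spec$arc[2], length.out = 181)
  xr <- range((spec$R + tMax / 2) * cos(th), (spec$R - tMax / 2) * cos(th))
  zr <- range((spec$R + tMax / 2) * sin(th), (spec$R - tMax / 2) * sin(th))
  yr <- c(-spec$capDepth, spec$L + spec$capDepth)
  ## half-voxel stagger keeps the analytic boundary planes between samples
  lo <- c(xr[1], yr[1], zr[1]) - 2 * spec$voxel + spec$voxel / 2 + jitter
  n <- ceiling((c(xr[2], yr[2], zr[2]) + 2 * spec$voxel - lo) / spec$voxel) + 1L
  aff <- diag(c(spec$voxel, 1))
  aff[1:3, 4] <- lo

  ## voxel-center world coordinates
  ix <- lo[1] + (seq_len(n[1]) - 1) * spec$voxel[1]
  iy <- lo[2] + (seq_len(n[2]) - 1) * spec$voxel[2]
  iz <- lo[3] + (seq_len(n[3]) - 1) * spec$voxel[3]
  X <- array(rep(ix, times = n[2] * n[3]), n)
  Y <- array(rep(rep(iy, each = n[1]), times = n[3]), n)
  Z <- array(rep(iz, each = n[1] * n[2]), n)
  r <- sqrt(X^2 + Z^2)
  theta <- atan2(Z, X)
  inArc <- theta >= spec$arc[1] & theta <= spec$arc[2]
  tLoc <- array(0, n)
  tLoc[inArc] <- phantomLocalThickness(spec, theta[inArc], Y[inArc])
  inSheet <- inArc & abs(r - spec$R) <= tLoc / 2
  lab <- array(0L, n)
  part <- phantomPartition(spec$arc)
  dial <- labelDialectTable("phantom")
  body <- inSheet & Y >= 0 & Y <= spec$L
  for (i in seq_len(nrow(part))) {
    sel <- body & theta >= part$thetaLo[i] &
      (theta < part$thetaHi[i] | i == nrow(part))
    lab[sel] <- dial[[part$name[i]]]
  }
  lab[inSheet & Y > spec$L & Y <= spec$L + spec$capDepth] <- dial[["head"]]
  lab[inSheet & Y < 0 & Y >= -spec$capDepth] <- dial[["tail"]]

  vol <- new("LabelVolume", data = lab, affine = aff, dialect = "phantom",
             labels = dial)
  ## theta(u_ml): the harmonic medial/lateral coordinate of a thin sheet of
  ## varying thickness follows the 1D conductance law du/dtheta ~ 1/t(theta)
  ## (flux conservation); closed-form quadrature of the analytic thickness.
  thq <- seq(spec$arc[1], spec$arc[2], length.out = 2001L)
  cond <- cumsum(1 / phantomLocalThickness(spec, thq, rep(spec$L / 2, 2001L)))
  cond <- (cond - cond[1]) / (cond[length(cond)] - cond[1])
  thetaFromUml <- stats::approxfun(cond, thq, rule = 2)
  ## validity region of the sheet model: exclude the ridge-taper zone plus a
  ## boundary layer of ~2.5 local thicknesses, where the harmonic map
  ## degenerates and streamline thickness tends to zero by construction
  tEdge <- spec$thicknessFn(spec$arc, c(spec$L / 2, spec$L / 2))
  margin <- 3 * spec$ridgeWidth + 2.5 * tEdge / spec$R
  validTheta <- function(theta)
    theta >= spec$arc[1] + margin[1] & theta <= spec$arc[2] - margin[2]
  truth <- list(
    R = spec$R, arc = spec$arc, L = spec$L,
    thickness = function(theta, y) phantomLocalThickness(spec, theta, y),
    meanCurvature = 1 / (2 * spec$R),
    ridgeAngles = spec$arc,
    capPlanesY = c(0, spec$L),
    partition = part,
    midSheet = function(theta, y)
      cbind(spec$R * cos(theta), y, spec$R * sin(theta)),
    thetaFromUml = thetaFromUml,
    validTheta = validTheta,
    validUml = function(u) validTheta(thetaFromUml(u)),
    yFromUap = function(v) v * spec$L,
    spec = spec)
  list(volume = vol, truth = truth)
}

#' Generate the slab phantom
#'
#' An axis-aligned solid slab of extent a x b x t (medial/lateral x
#' longitudinal x thickness) with five equal pseudo-subfield bands along x
#' and head/tail caps along y. Ground truth: thickness `t` everywhere,
#' curvature 0, volume a*b*t.
#'
#' @param a,b,t slab extents in mm (x, y, z).
#' @param voxel voxel sizes in mm.
#' @param capDepth cap length (mm).
#' @return list with `volume` and `truth`.
#' @export
makeSlabPhantom <- function(a = 20, b = 30, t = 3,
                            voxel = c(0.5, 0.5, 0.5), capDepth = 2) {
  stopifnot(a > 0, b > 0, t > 0, all(voxel > 0))
  if (t <= 2 * voxel[3])
    hsError("phantom", "slab thickness %.2f mm not resolvable at %.2f mm voxels",
            t, voxel[3])
  lo <- -2 * voxel + voxel / 2 + c(0, -capDepth, 0)
  hi <- c(a, b + capDepth, t) + 2 * voxel
  n <- ceiling((hi - lo) / voxel) + 1L
  aff <- diag(c(voxel, 1)); aff[1:3, 4] <- lo
  ix <- lo[1] + (seq_len(n[1]) - 1) * voxel[1]
  iy <- lo[2] + (seq_len(n[2]) - 1) * voxel[2]
  iz <- lo[3] + (seq_len(n[3]) - 1) * voxel[3]
  X <- array(rep(ix, times = n[2] * n[3]), n)
  Y <- array(rep(rep(iy, each = n[1]), times = n[3]), n)
  Z <- array(rep(iz, each = n[1] * n[2]), n)
  inX <- X >= 0 & X <= a
  inZ <- Z >= 0 & Z <= t
  lab <- array(0L, n)
  dial <- labelDialectTable("phantom")
  breaks <- seq(0, a, length.out = 6L)
  body <- inX & inZ & Y >= 0 & Y <= b
  for (i in 1:5) {
    sel <- body & X >= breaks[i] & (X < breaks[i + 1] | i == 5L)
    lab[sel] <- dial[[bodySubfieldNames[i]]]
  }
  lab[inX & inZ & Y > b & Y <= b + capDepth] <- dial[["head"]]
  lab[inX & inZ & Y < 0 & Y >= -capDepth] <- dial[["tail"]]
  vol <- new("LabelVolume", data = lab, affine = aff, dialect = "phantom",
             labels = dial)
  truth <- list(a = a, b = b, t = t, thickness = t, meanCurvature = 0,
                volume = a * b * t, capPlanesY = c(0, b),
                ## sheet-model validity: outside a boundary layer of 2.5
                ## thicknesses from the medial/lateral edges (u_ml is linear
                ## in x for constant thickness)
                validUml = function(u) u * a >= 2.5 * t & u * a <= a - 2.5 * t)
  list(volume = vol, truth = truth)
}

#' Simulate a cohort of thickness maps with known group effects
#'
#' Fast-path cohort generator for statistical testing: each subject receives
#' the phantom's analytic base thickness map plus (for the affected group) a
#' patch thinning of depth `delta`, spatially smooth Gaussian noise, a
#' random medial/lateral shift (to exercise the alignment step), covariates
#' (age, sex) with configurable thickness coefficients, and a scalar
#' "hippocampal volume" carrying a separate group effect. Fully determined
#' by `seed`.
#'
#' @param nPerGroup named integer vector, e.g. `c(CU = 50, MCI = 50)`; the
#'   first group is the reference (unaffected) group.
#' @param delta patch thinning depth (mm) applied to the non-reference
#'   groups.
#' @param patch list with `i` and `j` index ranges (inclusive) of the
#'   thinned patch on the N x M grid.
#' @param sigma standard deviation of the smooth thickness noise (mm).
#' @param shiftRange subjects receive an integer medial/lateral shift drawn
#'   uniformly from `-shiftRange..shiftRange` grid cells.
#' @param N,M grid dimensions.
#' @param baseSpec phantom specification providing the base geometry.
#' @param ageCoef thickness change per year of age (mm/yr).
#' @param volumeDelta relative group reduction of the volume covariate.
#' @param volumeSigma relative noise of the volume covariate.
#' @param seed integer seed.
#' @return list of subjects; each has `id`, `group`, `thickness` (N x M),
#'   `curvature` (N x M), `shift`, `age`, `sex`, `volume`.
#' @export
simulateCohort <- function(nPerGroup = c(CU = 50, MCI = 50), delta = 0.5,
                           patch = list(i = c(12, 22), j = c(6, 15)),
                           sigma = 0.3, shiftRange = 3L, N = 40L, M = 20L,
                           baseSpec = phantomSpec(
                             thicknessFn = function(theta, y) 2 + sin(theta)),
                           ageCoef = -0.01, volumeDelta = 0.05,
                           volumeSigma = 0.05, seed = 1L) {
  N <- as.integer(N); M <- as.integer(M)
  if (delta > 0 && (max(patch$i) > N || max(patch$j) > M || min(patch$i) < 1 ||
                    min(patch$j) < 1))
    hsError("phantom", "thinning patch exceeds the %d x %d grid", N, M)
  uml <- (seq_len(N) - 0.5) / N
  uap <- (seq_len(M) - 0.5) / M
  theta <- baseSpec$arc[1] + uml * diff(baseSpec$arc)
  base <- matrix(phantomLocalThickness(baseSpec, rep(theta, M),
                                       rep(uap * baseSpec$L, each = N)), N, M)
  if (delta > 0 && delta >= min(base))
    hsError("phantom", "delta %.2f mm exceeds the minimum base thickness", delta)
  ## curvature profile: 1/(2R) plus sharp bumps at the ridge angles
  curvProf <- 1 / (2 * baseSpec$R) +
    0.5 * (exp(-(theta - baseSpec$arc[1])^2 / (2 * baseSpec$ridgeWidth^2)) +
           exp(-(theta - baseSpec$arc[2])^2 / (2 * baseSpec$ridgeWidth^2)))
  patchMask <- matrix(0, N, M)
  if (delta > 0)
    patchMask[patch$i[1]:patch$i[2], patch$j[1]:patch$j[2]] <- 1
  groups <- rep(names(nPerGroup), nPerGroup)
  baseVol <- sum(base) * 2            # arbitrary but fixed volume scale
  withSeed(seed, function() {
    lapply(seq_along(groups), function(s) {
      g <- groups[s]
      affected <- g != names(nPerGroup)[1]
      age <- stats::rnorm(1, 70 + 3 * affected, 5)
      sex <- stats::rbinom(1, 1, 0.5)
      shift <- sample(seq(-shiftRange, shiftRange), 1)
      noise <- matrix(stats::rnorm(N * M), N, M)
      sm <- gaussianSmooth3D(array(noise, c(N, M, 1)), c(1.5, 1.5, 0))[, , 1]
      sm <- sm / stats::sd(sm) * sigma
      thick <- base - (if (affected) delta else 0) * patchMask +
        ageCoef * (age - 70) + sm
      ## apply the subject's medial/lateral shift by row interpolation
      thick <- shiftMapRows(thick, shift)
      curv <- shiftMapRows(matrix(curvProf, N, M), shift) +
        matrix(stats::rnorm(N * M, 0, 0.1 * diff(range(curvProf))), N, M)
      vol <- baseVol * (1 - (if (affected) volumeDelta else 0)) *
        (1 + stats::rnorm(1, 0, volumeSigma))
      list(id = sprintf("subj%03d", s), group = g,
           thickness = pmax(thick, 0), curvature = curv, shift = shift,
           age = age, sex = sex, volume = vol)
    })
  })
}

## Shift every anterior/posterior row of an N x M map by `s` grid cells
## along the medial/lateral axis (linear interpolation, edge extension).
## Positive s moves features towards higher i.
shiftMapRows <- function(map, s) {
  N <- nrow(map)
  src <- pmin(pmax(seq_len(N) - s, 1), N)
  lo <- floor(src); hi <- ceiling(src); f <- src - lo
  map[lo, , drop = FALSE] * (1 - f) + map[hi, , drop = FALSE] * f
}
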