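---
title: "Geometry-based unfolding and thickness analysis of the hippocampal body"
author: "hipposheet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-based unfolding and thickness analysis of the hippocampal body}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

The hippocampus is a thin, curved sheet of gray matter rolled up inside the
medial temporal lobe: the subiculum and the CA1–CA3 subfields form an outer
lamina wrapped around CA4 and the dentate gyrus, separated from them by the
SRLM (stratum radiatum/lacunosum/moleculare). Volumetry collapses this
geometry into one number per subfield. `hipposheet` instead models the
hippocampal *body* — the mid-portion between head and tail — as a sheet,
builds an intrinsic coordinate system on it, and measures local thickness,
curvature and shape descriptors in a reference frame that is comparable
across subjects without image registration.

The processing chain is:

1. **Shape definition** (`prepareBodyMask`): the presubiculum, subiculum,
   CA1, CA2 and CA3 labels are merged (CA4/DG are anatomically distinct and
   excluded); molecular-layer voxels, when present, are reassigned to the
   nearest body subfield by Euclidean distance in world millimetres; the
   anterior/posterior extent is taken from head/tail labels when the
   segmentation provides them, otherwise from the most anterior slice
   carrying CA2 or CA3 and the most posterior slice carrying CA1 together
   with CA2/CA3; a repeated morphological closure (6-connected, 2
   iterations by default) removes small holes and protrusions.
2. **Meshing** (`extractSmoothSurface` / `tetrahedralize`): a smoothed
   iso-surface of the binarized body together with a conforming tetrahedral
   mesh of its interior.
3. **Boundary detection** (`anisotropicLaplaceEigenfunction`,
   `deriveBoundarySpec`): the surface is cut open at the head/tail
   transitions; on the resulting open cylinder the first non-constant
   eigenfunction of a curvature-aware anisotropic Laplace–Beltrami operator
   (natural/Neumann boundary conditions) is computed. Its zero level set
   consists of two curves running from ring to ring; the anisotropy draws
   them onto the two longitudinal high-curvature folds, which are precisely
   the medial boundary `C_m` (presubiculum/entorhinal transition) and the
   lateral boundary `C_l` (CA3/CA4 transition). The curves split the
   surface into an interior (SRLM-facing) and an exterior patch.
4. **Parametrization** (`buildCoordinateSystem`): three volumetric Laplace
   problems (linear FEM, Dirichlet 0/1 on opposing boundary entities,
   Neumann elsewhere) yield harmonic coordinates u_ml (medial to lateral,
   0 on `C_m`, 1 on `C_l`), u_ap (posterior to anterior, on the cut
   cross-sections) and u_ie (interior to exterior, on the two patches) —
   a harmonic map of the body onto a degenerated unit cube, bijective away
   from the two boundary curves (Radó–Kneser–Choquet).
5. **Grid and features** (`sampleMidsurfaceGrid`, `computeThicknessMap`,
   `computeCurvatureMap`, `geometricSummaries`): the mid-surface is the 0.5
   level set of u_ie; a regular N×M grid (40×20 by convention) is placed in
   (u_ml, u_ap); thickness at each grid point is the arc length of the
   u_ie gradient streamline through it, from the interior to the exterior
   boundary; mean curvature is computed with the discrete
   mean-curvature-normal (cotangent) operator, signed positive where the
   sheet is convex towards the exterior. Scalar volumes (fMRI, PET) can be
   sampled onto the same grid (`projectScalarVolume`).
6. **Group analysis** (`alignThicknessMaps`, `vertexwiseGLM`,
   `fdr2Correct`, `incrementalClassification`): curvature profiles
   (averaged over the anterior/posterior dimension) are aligned across
   subjects along the medial/lateral axis before grid-point-wise linear
   models; multiple comparisons are controlled by Benjamini–Hochberg
   step-up applied jointly across the two hemispheres' grids of a contrast
   ("FDR2"); the added classification value of thickness beyond volume is
   assessed with a likelihood-ratio test between nested logistic models.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `closureIterations` | 2 | – | dilation/erosion rounds closing segmentation holes |
| `implicitSigma` | 1 | voxels | Gaussian width of the implicit function before iso-extraction |
| `smoothingIterations` | 10 | – | Taubin-pair relaxation rounds (λ = 0.5, capped at one voxel diagonal) |
| `anisotropy` | (8, 2) | mm | conductivity weights 1/(1+α₁·k_max) across and (1+α₂·k_min) along the principal curvature directions |
| `eigenK` | 5 | – | eigenfunctions examined for the two-curve zero-set rule |
| `N`, `M` | 40, 20 | – | mid-surface grid (medial/lateral × anterior/posterior) |
| `sMax` | 5 | cells | alignment shift bound (12.5% of N = 40) |
| `q` | 0.05 | – | FDR level |

The anisotropy defaults were fixed by requiring, on the synthetic shell
phantom, that at least 80% of the eigenfunction's zero-set vertices fall in
the top quartile of surface curvature; with `anisotropy = c(0, 0)` the
operator reduces exactly to the cotangent Laplacian (this reduction is a
regression test). The grid is cell-centered, u = (i−0.5)/N, deliberately
avoiding the two boundary curves where the harmonic map degenerates.

## Meshing design

No tetrahedral mesh generator is bundled; the volume mesh is generated
directly from the voxel lattice. The binary mask is turned into an implicit
function by Gaussian smoothing (σ = 1 voxel per axis; if thresholding the
smoothed field would change the foreground component count — as for
isolated voxels or very thin structures — σ is halved repeatedly, down to
the raw binary field), every lattice cell is subdivided into six
tetrahedra (Freudenthal/Kuhn scheme, conforming across cells), and each
tetrahedron is clipped against the 0.5 iso-level
(marching tetrahedra; shared cut quads are triangulated by a
minimum-vertex-index diagonal rule, so neighboring cells agree). The
boundary of the clipped complex *is* the extracted surface — surface and
volume mesh conform by construction, which makes the surface-to-volume
transfer of Dirichlet sets exact. The implicit function is extended past
the head/tail cut planes by slice replication and the lattice is truncated
there, so the cut cross-sections are planar; their index coordinate is
stretched by half a voxel so the cut planes coincide with the outer faces
of the end slices. Mild vertex relaxation in volume-conserving
shrink/inflate pairs (Taubin-style, λ = 0.5 / μ = −0.52; surface vertices
along the surface graph, interior vertices along the tet-edge graph, cap
vertices kept in their plane, total movement capped at one voxel diagonal,
globally damped if any tetrahedron would invert) removes the remaining
staircase without shrinking the body — on a digitized ball the
before/after surface area and enclosed volume agree to about 0.1%.
`tetrahedralize()` on a stand-alone closed surface falls back to a
centroid-fan construction, valid for star-shaped surfaces and verified
through tetrahedron orientations.

Marching tetrahedra was chosen over classic marching cubes because it has
no ambiguous cell configurations and yields the conforming interior mesh in
the same pass; the substance — the 0.5 iso-surface of the (smoothed)
binarized segmentation — is unchanged.

## Numerical choices

* **FEM**: linear (P1) elements; the reduced symmetric positive-definite
  systems are solved by sparse Cholesky (fill-reducing permutation), with a
  1e-9 relative-residual guard. P1 reproduces linear fields exactly — the
  unit-cube check in the test suite is exact to machine precision.
* **Eigenproblem**: lumped (barycentric) mass; for meshes above ~900
  vertices the smallest eigenpairs are obtained by shift-invert ARPACK
  iterations on the mass-normalized operator, below that by dense
  symmetric eigendecomposition. Selection rule: smallest-eigenvalue
  non-constant eigenfunction whose zero set has exactly two ring-to-ring
  components (stray components shorter than 10% of the longest are
  ignored); the sign is fixed to be positive over subiculum-labeled
  vertices.
* **Maximum principle**: solved coordinates are checked against [0, 1];
  excursions (possible with obtuse tets) are reported via an attribute and
  clipped only for level-set extraction, never silently.
* **Streamlines**: with P1 elements the u_ie gradient is piecewise
  constant; directly following it ping-pongs across sliver tetrahedra, so
  the tracer integrates the volume-weighted vertex-averaged gradient field
  (RK2, step = 1/4 mean tet edge) with tet-walk relocation and exact
  clipping at the boundary. On a constant-gradient slab this is exact; on
  the cylindrical annulus the radial path length is recovered within 2%.
* **Ties and degeneracies**: nearest-label assignment breaks ties towards
  the lowest label code; the interior/exterior patch is the one whose
  normals face the body centroid, with a deterministic inferior-side
  fallback (and a warning) for perfectly flat sheets, where that criterion
  is degenerate; iso-level cut parameters are clamped to [0.02, 0.98] to
  avoid degenerate slivers.
* **Summary measures**: inner/outer cross-section lengths are taken on the
  u_ie = 0.01 / 0.99 level surfaces (avoiding cap contamination of the raw
  mesh boundary); the interior/exterior ratio is computed over the central
  90% of the medial/lateral range, because the two surfaces meet at the
  rims and the arc ratio — unlike the circumference — is scale-invariant
  and needs no rim contribution; slice (ribbon) areas are normalized by
  the level span. The image-based thickness oracle integrates its
  streamlines until the trilinear mask indicator crosses 0.5, so both
  methods measure boundary-to-boundary distance.
* **Alignment**: maximal Pearson correlation over fractional shifts (step
  0.05 cells) computed on the non-extrapolated overlap; with
  `reference = "mean"` the procedure iterates twice. Alignment to a mean
  reference is only identified up to a common translation; evaluations
  against known shifts therefore use an explicit reference profile.

## What the phantom emulates — and what it does not

The curved-shell phantom voxelizes a cylindrical-shell sector (mid-sheet
radius R = 15 mm, 180° arc, 30 mm body length, thickness field t(θ, y),
default 2.5 mm or 2 + sin θ) on an anisotropic grid of 0.5 × 1.5 × 0.5 mm
voxels — the in-plane/slice geometry of high-resolution T2 hippocampal
imaging — with pseudo-subfield labels in five equal angular bands,
head/tail caps, and longitudinal ridges at the sheet edges realised as a
local thickness taper (sharpened rims raise the local surface curvature,
giving the anisotropic eigenfunction its attractors). Ground truth
(mid-sheet, thickness, curvature 1/(2R), ridge angles, the mapping between
intrinsic coordinates and (θ, y)) is analytic throughout and never derived
from the pipeline.

Two aspects of the ground truth deserve emphasis:

* **θ(u_ml) follows the thin-sheet conductance law.** The harmonic
  medial/lateral coordinate of a sheet with varying thickness satisfies
  (t·u')' = 0 in the thin-sheet limit, i.e. du/dθ ∝ 1/t(θ); the truth
  mapping is the closed-form quadrature of the analytic thickness, not a
  linear map in θ.
* **The sheet model has a boundary layer.** The harmonic map is degenerate
  at the two boundary curves, and streamline thickness tends to zero as a
  grid point approaches them — a property of the model (visible in real
  flat maps as thin borders), not an artifact. The phantom therefore
  defines a validity region — the sheet interior, excluding the ridge
  taper zone plus a boundary layer of 2.5 local thicknesses — over which
  point-wise recovery is assessed; over that region the slab phantom is
  recovered to better than 0.1% and the varying-thickness shell to a
  median point-wise error of about 2%.

The phantom does **not** emulate: MR intensities and segmentation noise,
the sideways folding of the hippocampal head, subfield boundary
uncertainty, or topological defects (those are exercised by dedicated
defective fixtures). Passing phantom tests therefore demonstrates that the
geometric machinery is correct at the acquisition geometry it models — not
that any particular clinical segmentation is adequate.

The cohort simulator (`simulateCohort`) operates in grid space: it takes
the phantom's analytic thickness map, applies a group-specific patch
thinning, spatially smooth Gaussian noise, a random medial/lateral shift
(exercising the alignment step), age/sex covariates with configurable
coefficients, and a scalar "volume" with its own group effect, all
deterministically from one seed. Statistical calibration (family-level
false-positive rate of the FDR pipeline, uniformity of the
likelihood-ratio p under the null) and effect localization (Dice of the
significant set against the simulated patch) are assessed on it. Problem
sizes used in the shipped tests — 200 null replicates at n = 10+10, one
effect cohort at n = 50+50, 500 likelihood-ratio nulls at n = 100 — were
chosen as the smallest sizes at which these sampling-based checks are
stable.

## Known limitations

* Only the hippocampal body is modeled; head and tail are cut away (at
  current resolutions the head folds onto itself and the tail lacks
  detail).
* Thickness near the medial/lateral boundary curves is attenuated by
  construction; analyses of the sheet border should use the interior of
  the grid or coarser row summaries.
* The pipeline refuses topologically defective masks (disconnected
  foreground, internal cavities, genus > 0 surfaces) with documented exit
  codes instead of attempting repair.
* The conductivity form of the anisotropic operator (weights
  1/(1+α₁|k_max|), 1+α₂|k_min|) is one of several reasonable
  curvature-aware choices; it is constrained by the isotropic-reduction
  identity and the ridge-attraction test rather than by a unique
  derivation.
* Equivolumetric (rather than equipotential) laminar spacing is not
  implemented; it would change layer placement but not the streamline
  thickness itself.

## Reproducing the numbers

```{r example}
library(hipposheet)

## synthetic subject with known geometry
ph <- makeCurvedShellPhantom(
  phantomSpec(thicknessFn = function(theta, y) 2 + sin(theta)))
res <- runPipeline(ph$volume, "shell_out", dialect = "phantom")
res$summary
thicknessValues(res$grid)[20, 10]    # mid-sheet point, ~3 mm

## group analysis on a simulated cohort
co <- simulateCohort(nPerGroup = c(CU = 50, MCI = 50), delta = 0.5,
                     sigma = 0.3, seed = 7)
al <- alignThicknessMaps(co)
des <- data.frame(group = sapply(co, `[[`, "group"),
                  age = sapply(co, `[[`, "age"),
                  sex = sapply(co, `[[`, "sex"))
stat <- vertexwiseGLM(lapply(al$subjects, `[[`, "thickness"), des)
stat
```

The acceptance script (`scripts/acceptance.R`) re-runs all of the above
from scratch — FEM oracles, phantom recovery, boundary detection quality,
cross-method thickness agreement, alignment and statistical calibration,
determinism and rigid-motion invariance — and writes the quantities to a
JSON report; see the README for how to invoke it.
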