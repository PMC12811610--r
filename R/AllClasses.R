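## Central S4 data containers of the hipposheet pipeline.

#' LabelVolume: a labeled segmentation volume
#'
#' A 3D integer label grid together with its voxel-to-world affine and the
#' label dialect (a named integer vector mapping anatomical names such as
#' `subiculum` or `CA1` to integer codes).
#'
#' @slot data 3D integer array of label codes (0 = background).
#' @slot affine 4x4 voxel-to-world transform; voxel indices are 0-based in
#'   the NIfTI convention, i.e. world = affine %*% c(i-1, j-1, k-1, 1) for
#'   R indices (i,j,k).
#' @slot dialect name of the label dialect ("freesurfer", "ashs", "phantom",
#'   or a custom name).
#' @slot labels named integer vector: anatomical name -> label code.
#'
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(data = "array", affine = "matrix",
                 dialect = "character", labels = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    else if (abs(det(object@affine)) < 1e-12)
      msg <- c(msg, "affine must be invertible")
    if (any(object@data < 0, na.rm = TRUE))
      msg <- c(msg, "label codes must be non-negative")
    if (is.null(names(object@labels)) && length(object@labels))
      msg <- c(msg, "labels must be a named integer vector")
    if (length(msg)) msg else TRUE
  })

#' BodyMask: binary mask of the hippocampal body
#'
#' The cleaned, cropped, binarized hippocampal body, together with the
#' anterior/posterior axis and the slice range delimiting the body. The cut
#' faces towards head and tail ("caps") are implied by the slice range.
#'
#' @slot mask 3D logical array (stored as array of logicals).
#' @slot affine 4x4 voxel-to-world transform (as in [LabelVolume-class]).
#' @slot apAxis integer in 1:3, the voxel axis most aligned with the world
#'   anterior/posterior (y) axis.
#' @slot apRange integer(2): first and last slice index (along `apAxis`)
#'   of the body; the caps sit on the outer faces of these slices.
#' @slot anteriorEnd which end of `apRange` is anterior: 1 or 2.
#'
#' @exportClass BodyMask
setClass("BodyMask",
  representation(mask = "array", affine = "matrix", apAxis = "integer",
                 apRange = "integer", anteriorEnd = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@mask)) != 3L)
      msg <- c(msg, "mask must be a 3D array")
    if (!is.logical(object@mask))
      msg <- c(msg, "mask must be logical")
    if (!(object@apAxis %in% 1:3))
      msg <- c(msg, "apAxis must be 1, 2 or 3")
    if (length(object@apRange) != 2L || object@apRange[1] > object@apRange[2])
      msg <- c(msg, "apRange must be an increasing pair of slice indices")
    if (!(object@anteriorEnd %in% 1:2))
      msg <- c(msg, "anteriorEnd must be 1 or 2")
    if (length(msg)) msg else TRUE
  })

#' TriangleSurface: a triangle mesh in world coordinates
#'
#' @slot vertices n x 3 numeric matrix of vertex positions (mm).
#' @slot triangles m x 3 integer matrix of vertex indices (1-based),
#'   consistently oriented with outward normals for closed surfaces.
#' @slot vertexData data.frame with one row per vertex; standard columns are
#'   `subfield` (integer label code or NA), `cap` (character:
#'   "anterior"/"posterior"/NA), and `tetVertex` (index into the parent
#'   tetrahedral mesh, if any).
#'
#' @exportClass TriangleSurface
setClass("TriangleSurface",
  representation(vertices = "matrix", triangles = "matrix",
                 vertexData = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (ncol(object@triangles) != 3L) msg <- c(msg, "triangles must be m x 3")
    if (nrow(object@triangles) &&
        (min(object@triangles) < 1L ||
         max(object@triangles) > nrow(object@vertices)))
      msg <- c(msg, "triangle indices out of range")
    if (nrow(object@vertexData) &&
        nrow(object@vertexData) != nrow(object@vertices))
      msg <- c(msg, "vertexData must have one row per vertex")
    if (length(msg)) msg else TRUE
  })

#' OpenSurface: a surface cut open at the head/tail transitions
#'
#' A [TriangleSurface-class] with cylinder topology (Euler characteristic 0)
#' and exactly two boundary loops, the anterior and posterior cut rings.
#'
#' @slot boundaryLoops named list of two integer vectors ("anterior",
#'   "posterior"), each an ordered closed ring of vertex indices.
#'
#' @exportClass OpenSurface
setClass("OpenSurface", contains = "TriangleSurface",
  representation(boundaryLoops = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@boundaryLoops) != 2L)
      msg <- c(msg, "an open surface must have exactly two boundary loops")
    if (!all(c("anterior", "posterior") %in% names(object@boundaryLoops)))
      msg <- c(msg, "boundary loops must be named anterior/posterior")
    if (length(msg)) msg else TRUE
  })

#' TetrahedralMesh: a conforming tetrahedral volume mesh
#'
#' @slot vertices n x 3 numeric matrix (mm, world frame).
#' @slot tets k x 4 integer matrix; all tets positively oriented.
#' @slot boundaryTriangles m x 3 integer matrix, the conforming boundary
#'   surface (outward oriented), indexing into `vertices`.
#' @slot vertexData data.frame, one row per vertex (`subfield`, `cap`).
#'
#' @exportClass TetrahedralMesh
setClass("TetrahedralMesh",
  representation(vertices = "matrix", tets = "matrix",
                 boundaryTriangles = "matrix", vertexData = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (ncol(object@tets) != 4L) msg <- c(msg, "tets must be k x 4")
    if (nrow(object@tets) && max(object@tets) > nrow(object@vertices))
      msg <- c(msg, "tet indices out of range")
    if (ncol(object@boundaryTriangles) != 3L)
      msg <- c(msg, "boundaryTriangles must be m x 3")
    if (length(msg)) msg else TRUE
  })

#' SurfaceEigenfunction: eigenfunction of the (anisotropic) surface Laplacian
#'
#' @slot values one real value per vertex of the open surface.
#' @slot eigenvalue the associated non-negative eigenvalue.
#' @slot anisotropy numeric(2), the (alpha1, alpha2) conductivity parameters;
#'   c(0, 0) gives the standard cotangent Laplace-Beltrami operator.
#' @slot index which eigenpair (1 = constant mode) was selected.
#'
#' @exportClass SurfaceEigenfunction
setClass("SurfaceEigenfunction",
  representation(values = "numeric", eigenvalue = "numeric",
                 anisotropy = "numeric", index = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@anisotropy) != 2L)
      msg <- c(msg, "anisotropy must be a pair")
    if (length(object@eigenvalue) != 1L || object@eigenvalue < -1e-8)
      msg <- c(msg, "eigenvalue must be a single non-negative number")
    if (length(msg)) msg else TRUE
  })

#' BoundarySpec: the six boundary entities of the hippocampal body
#'
#' Vertex indices refer to the [OpenSurface-class] the spec was derived from.
#'
#' @slot cm ordered vertex path of the medial curve (presubiculum side).
#' @slot cl ordered vertex path of the lateral curve (CA3 side).
#' @slot anteriorRing,posteriorRing ordered vertex rings of the cut faces.
#' @slot interiorTriangles,exteriorTriangles disjoint triangle index sets
#'   covering the open surface (SRLM-facing vs outer patch).
#'
#' @exportClass BoundarySpec
setClass("BoundarySpec",
  representation(cm = "integer", cl = "integer",
                 anteriorRing = "integer", posteriorRing = "integer",
                 interiorTriangles = "integer", exteriorTriangles = "integer"),
  validity = function(object) {
    msg <- character()
    if (!length(object@cm) || !length(object@cl))
      msg <- c(msg, "both boundary curves must be non-empty")
    if (length(intersect(object@interiorTriangles, object@exteriorTriangles)))
      msg <- c(msg, "interior and exterior patches must be disjoint")
    if (length(msg)) msg else TRUE
  })

#' ScalarField: a Laplace coordinate field on the tetrahedral mesh
#'
#' @slot values one real per tet-mesh vertex, in [0, 1] up to clipping
#'   tolerance; exactly 0/1 on the Dirichlet sets.
#' @slot axis one of "medial_lateral", "anterior_posterior",
#'   "interior_exterior".
#' @slot zeroSet,oneSet vertex index sets carrying the Dirichlet values.
#'
#' @exportClass ScalarField
setClass("ScalarField",
  representation(values = "numeric", axis = "character",
                 zeroSet = "integer", oneSet = "integer"),
  validity = function(object) {
    msg <- character()
    ok <- c("medial_lateral", "anterior_posterior", "interior_exterior")
    if (!(object@axis %in% ok))
      msg <- c(msg, paste("axis must be one of:", paste(ok, collapse = ", ")))
    if (length(intersect(object@zeroSet, object@oneSet)))
      msg <- c(msg, "Dirichlet sets must be disjoint")
    if (length(object@values)) {
      if (any(abs(object@values[object@zeroSet]) > 1e-12))
        msg <- c(msg, "values on zeroSet must be exactly 0")
      if (any(abs(object@values[object@oneSet] - 1) > 1e-12))
        msg <- c(msg, "values on oneSet must be exactly 1")
    }
    if (length(msg)) msg else TRUE
  })

#' CoordinateSystem: the intrinsic coordinates of the hippocampal body
#'
#' Three harmonic scalar fields on one shared tetrahedral mesh, mapping the
#' body to a degenerated unit cube: medial->lateral, posterior->anterior and
#' interior->exterior all increase from 0 to 1.
#'
#' @slot mesh the shared [TetrahedralMesh-class].
#' @slot uml,uap,uie the three [ScalarField-class] coordinates.
#'
#' @exportClass CoordinateSystem
setClass("CoordinateSystem",
  representation(mesh = "TetrahedralMesh", uml = "ScalarField",
                 uap = "ScalarField", uie = "ScalarField"),
  validity = function(object) {
    n <- nrow(object@mesh@vertices)
    if (length(object@uml@values) != n || length(object@uap@values) != n ||
        length(object@uie@values) != n)
      "all three fields must live on the mesh vertices" else TRUE
  })

#' ThicknessGrid: the N x M mid-surface analysis grid
#'
#' The primary analysis object: a regular grid in the (medial/lateral,
#' anterior/posterior) parameter plane, sampled on the 0.5 level set of the
#' interior/exterior coordinate, with streamline thickness and signed mean
#' curvature per grid point.
#'
#' @slot N,M grid dimensions (medial/lateral x anterior/posterior).
#' @slot uml,uap the prescribed cell-centered parameter lattices,
#'   (i - 0.5)/N and (j - 0.5)/M.
#' @slot points (N*M) x 3 matrix of mid-surface positions (mm), row index
#'   k = (j-1)*N + i.
#' @slot uie interpolated interior/exterior coordinate at each point.
#' @slot thickness,curvature N x M numeric matrices (mm, 1/mm); may contain
#'   NA before the corresponding fill step.
#' @slot flags N x M integer matrix: 0 = ok, 1 = imputed/flagged.
#'
#' @exportClass ThicknessGrid
setClass("ThicknessGrid",
  representation(N = "integer", M = "integer", uml = "numeric",
                 uap = "numeric", points = "matrix", uie = "numeric",
                 thickness = "matrix", curvature = "matrix",
                 flags = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@points) != object@N * object@M)
      msg <- c(msg, "points must have N*M rows")
    if (length(object@uml) != object@N || length(object@uap) != object@M)
      msg <- c(msg, "uml/uap lattices must have N/M entries")
    if (any(object@thickness < 0, na.rm = TRUE))
      msg <- c(msg, "thickness must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' GeometrySummary: scalar shape measures of one hippocampal body
#'
#' @slot lengthX,lengthY,lengthZ medial/lateral extent, anterior/posterior
#'   extent, and mean thickness (mm).
#' @slot circumference inner + outer cross-section length, mean over
#'   anterior/posterior rows (mm).
#' @slot interiorExteriorRatio inner/outer cross-section length ratio.
#' @slot surfaceArea total exterior surface area (mm^2).
#' @slot shapeIndex circumference / surfaceArea (1/mm).
#' @slot rowTable data.frame with per-row inner/outer lengths, circumference,
#'   ratio and slice area.
#'
#' @exportClass GeometrySummary
setClass("GeometrySummary",
  representation(lengthX = "numeric", lengthY = "numeric",
                 lengthZ = "numeric", circumference = "numeric",
                 interiorExteriorRatio = "numeric", surfaceArea = "numeric",
                 shapeIndex = "numeric", rowTable = "data.frame"))

#' GridStatResult: grid-point-wise statistics of a group contrast
#'
#' @slot t,p,pAdjusted,significant N x M matrices (t statistic, raw p,
#'   FDR-adjusted p, logical significance mask).
#' @slot peak integer(2): 1-based (x = medial/lateral index, y =
#'   anterior/posterior index) of the maximal |t| among significant points
#'   (or overall if none significant).
#' @slot df residual degrees of freedom of the fit.
#'
#' @exportClass GridStatResult
setClass("GridStatResult",
  representation(t = "matrix", p = "matrix", pAdjusted = "matrix",
                 significant = "matrix", peak = "integer", df = "numeric"),
  validity = function(object) {
    if (any(object@pAdjusted < object@p - 1e-12, na.rm = TRUE))
      "adjusted p must be >= raw p" else TRUE
  })
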