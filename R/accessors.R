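## Accessors and show() methods. Slot access from user code should go
## through these.

#' Accessors for hipposheet objects
#'
#' Small read-only accessors for the S4 containers: mesh geometry
#' (`vertices`, `triangles`, `tetrahedra`, `vertexData`, `boundaryLoops`),
#' volumes (`affine`, `labelData`, `labelDialect`, `maskArray`), coordinate
#' fields (`fieldValues`), and grids (`gridPoints`, `gridDim`,
#' `thicknessValues`, `curvatureValues`).
#'
#' @param x a hipposheet object.
#' @return The corresponding slot content (matrices, arrays or data frames).
#' @name accessors
NULL

#' @rdname accessors
setMethod("vertices", "TriangleSurface", function(x) x@vertices)
#' @rdname accessors
setMethod("vertices", "TetrahedralMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("triangles", "TriangleSurface", function(x) x@triangles)
#' @rdname accessors
setMethod("triangles", "TetrahedralMesh", function(x) x@boundaryTriangles)
#' @rdname accessors
setMethod("tetrahedra", "TetrahedralMesh", function(x) x@tets)
#' @rdname accessors
setMethod("vertexData", "TriangleSurface", function(x) x@vertexData)
#' @rdname accessors
setMethod("vertexData", "TetrahedralMesh", function(x) x@vertexData)
#' @rdname accessors
setMethod("affine", "LabelVolume", function(x) x@affine)
#' @rdname accessors
setMethod("affine", "BodyMask", function(x) x@affine)
#' @rdname accessors
setMethod("labelData", "LabelVolume", function(x) x@data)
#' @rdname accessors
setMethod("labelDialect", "LabelVolume", function(x) x@labels)
#' @rdname accessors
setMethod("maskArray", "BodyMask", function(x) x@mask)
#' @rdname accessors
setMethod("fieldValues", "ScalarField", function(x) x@values)
#' @rdname accessors
setMethod("fieldValues", "SurfaceEigenfunction", function(x) x@values)
#' @rdname accessors
setMethod("thicknessValues", "ThicknessGrid", function(x) x@thickness)
#' @rdname accessors
setMethod("curvatureValues", "ThicknessGrid", function(x) x@curvature)
#' @rdname accessors
setMethod("gridPoints", "ThicknessGrid", function(x) x@points)
#' @rdname accessors
setMethod("gridDim", "ThicknessGrid", function(x) c(x@N, x@M))
#' @rdname accessors
setMethod("boundaryLoops", "OpenSurface", function(x) x@boundaryLoops)

#' @export
setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  vox <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat("LabelVolume:", paste(d, collapse = " x "),
      sprintf("voxels (%.2f x %.2f x %.2f mm), dialect '%s'\n",
              vox[1], vox[2], vox[3], object@dialect))
  tab <- table(object@data[object@data > 0])
  if (length(tab)) {
    nm <- names(object@labels)[match(as.integer(names(tab)), object@labels)]
    nm[is.na(nm)] <- "?"
    cat("  foreground codes:",
        paste(sprintf("%s(%s)=%d", names(tab), nm, as.integer(tab)),
              collapse = ", "), "\n")
  } else cat("  background only\n")
})

#' @export
setMethod("show", "BodyMask", function(object) {
  cat("BodyMask:", sum(object@mask), "foreground voxels in",
      paste(dim(object@mask), collapse = " x "), "grid\n")
  cat(sprintf("  anterior/posterior axis %d, body slices %d..%d (anterior at the %s end)\n",
              object@apAxis, object@apRange[1], object@apRange[2],
              if (object@anteriorEnd == 1L) "low" else "high"))
})

#' @export
setMethod("show", "TriangleSurface", function(object) {
  cat(class(object), ":", nrow(object@vertices), "vertices,",
      nrow(object@triangles), "triangles\n")
  ec <- surfaceEulerCharacteristic(object)
  cat("  Euler characteristic:", ec, "\n")
})

#' @export
setMethod("show", "TetrahedralMesh", function(object) {
  cat("TetrahedralMesh:", nrow(object@vertices), "vertices,",
      nrow(object@tets), "tets,", nrow(object@boundaryTriangles),
      "boundary triangles\n")
  cat(sprintf("  total volume %.2f mm^3\n", sum(tetVolumes(object))))
})

#' @export
setMethod("show", "SurfaceEigenfunction", function(object) {
  cat(sprintf("SurfaceEigenfunction: eigenpair %d, eigenvalue %.6g, anisotropy (%g, %g)\n",
              object@index, object@eigenvalue,
              object@anisotropy[1], object@anisotropy[2]))
})

#' @export
setMethod("show", "BoundarySpec", function(object) {
  cat("BoundarySpec: C_m", length(object@cm), "vertices, C_l",
      length(object@cl), "vertices;",
      length(object@anteriorRing), "/", length(object@posteriorRing),
      "ring vertices;", length(object@interiorTriangles), "interior /",
      length(object@exteriorTriangles), "exterior triangles\n")
})

#' @export
setMethod("show", "ScalarField", function(object) {
  cat(sprintf("ScalarField '%s': %d vertices, range [%.4g, %.4g]\n",
              object@axis, length(object@values),
              min(object@values), max(object@values)))
})

#' @export
setMethod("show", "CoordinateSystem", function(object) {
  cat("CoordinateSystem on", nrow(object@mesh@vertices), "vertices /",
      nrow(object@mesh@tets), "tets\n")
})

#' @export
setMethod("show", "ThicknessGrid", function(object) {
  cat(sprintf("ThicknessGrid %d x %d (medial/lateral x anterior/posterior)\n",
              object@N, object@M))
  if (!all(is.na(object@thickness)))
    cat(sprintf("  thickness: mean %.3f mm, range [%.3f, %.3f]\n",
                mean(object@thickness, na.rm = TRUE),
                min(object@thickness, na.rm = TRUE),
                max(object@thickness, na.rm = TRUE)))
  if (!all(is.na(object@curvature)))
    cat(sprintf("  curvature: mean %.4f 1/mm\n",
                mean(object@curvature, na.rm = TRUE)))
})

#' @export
setMethod("show", "GeometrySummary", function(object) {
  cat("GeometrySummary:\n")
  cat(sprintf("  extents (x, y): %.2f, %.2f mm; mean thickness (z): %.3f mm\n",
              object@lengthX, object@lengthY, object@lengthZ))
  cat(sprintf("  circumference %.2f mm, interior/exterior ratio %.3f\n",
              object@circumference, object@interiorExteriorRatio))
  cat(sprintf("  surface area %.1f mm^2, shape index %.4f 1/mm\n",
              object@surfaceArea, object@shapeIndex))
})

#' @export
setMethod("show", "GridStatResult", function(object) {
  cat(sprintf("GridStatResult: %d x %d grid, df = %g, %d significant points\n",
              nrow(object@t), ncol(object@t), object@df,
              sum(object@significant, na.rm = TRUE)))
  cat(sprintf("  peak |t| = %.3f at (x = %d, y = %d)\n",
              abs(object@t[object@peak[1], object@peak[2]]),
              object@peak[1], object@peak[2]))
})
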