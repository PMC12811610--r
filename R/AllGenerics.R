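## Generics for the accessor functions. Methods live in accessors.R.

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))

#' @rdname accessors
#' @export
setGeneric("tetrahedra", function(x) standardGeneric("tetrahedra"))

#' @rdname accessors
#' @export
setGeneric("vertexData", function(x) standardGeneric("vertexData"))

#' @rdname accessors
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @rdname accessors
#' @export
setGeneric("labelDialect", function(x) standardGeneric("labelDialect"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname accessors
#' @export
setGeneric("thicknessValues", function(x) standardGeneric("thicknessValues"))

#' @rdname accessors
#' @export
setGeneric("curvatureValues", function(x) standardGeneric("curvatureValues"))

#' @rdname accessors
#' @export
setGeneric("gridPoints", function(x) standardGeneric("gridPoints"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("boundaryLoops", function(x) standardGeneric("boundaryLoops"))
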