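#' Accessors for quatsym objects
#'
#' Small accessor generics used across the package instead of direct
#' slot access.
#'
#' @param x an object.
#' @param ... passed on to methods.
#' @return See the individual methods.
#' @name quatsym-accessors
NULL

#' @rdname quatsym-accessors
#' @export
setGeneric("atomTable", function(x, ...) standardGeneric("atomTable"))

#' @rdname quatsym-accessors
#' @export
setGeneric("nAtoms", function(x, ...) standardGeneric("nAtoms"))

#' @rdname quatsym-accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname quatsym-accessors
#' @export
setGeneric("chainIds", function(x, ...) standardGeneric("chainIds"))

#' @rdname quatsym-accessors
#' @export
setGeneric("nPeptides", function(x, ...) standardGeneric("nPeptides"))

#' @rdname quatsym-accessors
#' @export
setGeneric("peptideIndices", function(x, ...) standardGeneric("peptideIndices"))

#' @rdname quatsym-accessors
#' @export
setGeneric("centroid", function(x, ...) standardGeneric("centroid"))

#' @rdname quatsym-accessors
#' @export
setGeneric("csmValue", function(x, ...) standardGeneric("csmValue"))

#' @rdname quatsym-accessors
#' @export
setGeneric("symmetryAxis", function(x, ...) standardGeneric("symmetryAxis"))

#' @rdname quatsym-accessors
#' @export
setGeneric("atomPermutation", function(x, ...) standardGeneric("atomPermutation"))

#' @rdname quatsym-accessors
#' @export
setGeneric("peptidePermutation", function(x, ...) standardGeneric("peptidePermutation"))

#' @rdname quatsym-accessors
#' @export
setGeneric("nearestCoords", function(x, ...) standardGeneric("nearestCoords"))
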