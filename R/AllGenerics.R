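#' Accessors for panel and spectral containers
#'
#' @param object a package object.
#' @param ... further arguments for methods.
#' @return `concentrations()` the numeric concentration matrix;
#'   `belowLOQ()` the logical censoring mask; `featureMeta()` the per-feature
#'   metadata `DataFrame`; `loq()` the named LOQ vector; `subjectIds()` the
#'   subject identifiers; `binValues()` / `binEdges()` the bucketed matrix and
#'   its ppm windows.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("concentrations", function(object, ...)
  standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setGeneric("belowLOQ", function(object, ...) standardGeneric("belowLOQ"))

#' @rdname accessors
#' @export
setGeneric("featureMeta", function(object, ...) standardGeneric("featureMeta"))

#' @rdname accessors
#' @export
setGeneric("loq", function(object, ...) standardGeneric("loq"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object, ...) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("binValues", function(object, ...) standardGeneric("binValues"))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(object, ...) standardGeneric("binEdges"))
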