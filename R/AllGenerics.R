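#' @import methods
NULL

#' Gene identifiers of an object
#'
#' @param x an object carrying gene symbols (rows of an expression or
#'   centroid matrix, entries of a reference profile).
#' @return character vector of gene symbols.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Sample identifiers of an object
#'
#' @param x an object carrying sample identifiers.
#' @return character vector of sample identifiers.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Class (subtype) names of an object
#'
#' @param x an object carrying subtype class names.
#' @return character vector of class names, in the object's stored order.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' Numeric values of a matrix-like container
#'
#' @param x an `ExpressionMatrix` or `CentroidTable`.
#' @return the underlying numeric matrix (genes in rows).
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Subtype calls as a named character vector
#'
#' @param x a `SubtypeCallSet` (or a named character vector, returned as-is).
#' @return named character vector, sample id -> called class (possibly
#'   `"UNCLASSIFIABLE"`).
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' Per-class correlation (or membership) matrix of a call set
#'
#' @param x a `SubtypeCallSet`.
#' @return numeric matrix, samples x classes; `NA` for excluded classes.
#' @export
setGeneric("callScores", function(x) standardGeneric("callScores"))
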