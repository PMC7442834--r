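#' @include AllGenerics.R
NULL

# ---- ExpressionMatrix -------------------------------------------------------

#' Log2-scale expression matrix (genes x samples)
#'
#' Thin validated container for a dense log2-scale gene expression matrix.
#' Gene symbols are stored upper-cased and must be unique; sample identifiers
#' must be unique; every value must be finite. No normalization or transform
#' is ever applied implicitly: values are stored exactly as supplied.
#'
#' @slot values numeric matrix, genes in rows, samples in columns, with
#'   complete dimnames.
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

.validExpressionMatrix <- function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "gene and sample identifiers (dimnames) are required")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, paste0("duplicate gene identifier: ",
                           rownames(v)[duplicated(rownames(v))][1L]))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, paste0("duplicate sample identifier: ",
                           colnames(v)[duplicated(colnames(v))][1L]))
    if (!identical(rownames(v), toupper(rownames(v))))
      msg <- c(msg, "gene symbols must be stored upper-cased")
  }
  if (is.numeric(v) && !all(is.finite(v)))
    msg <- c(msg, "all expression values must be finite (no NA/NaN/Inf)")
  if (length(msg)) msg else TRUE
}
setValidity("ExpressionMatrix", .validExpressionMatrix)

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (genes x samples) with dimnames. Gene symbols
#'   are upper-cased on construction.
#' @return a validated [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("ESR1", "ERBB2", "MKI67"), c("s1", "s2")))
#' em <- ExpressionMatrix(m)
#' genes(em)
#' @export
ExpressionMatrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- toupper(rownames(values))
  new("ExpressionMatrix", values = values)
}

#' @rdname genes
#' @export
setMethod("genes", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' Subset an ExpressionMatrix by gene and/or sample
#'
#' @param x ExpressionMatrix
#' @param i gene index/names
#' @param j sample index/names
#' @param ... ignored
#' @param drop ignored; dimensions are always kept.
#' @export
setMethod("[", "ExpressionMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("ExpressionMatrix", values = v)
})

setMethod("show", "ExpressionMatrix", function(object) {
  d <- dim(object@values)
  cat("ExpressionMatrix: ", d[1L], " genes x ", d[2L], " samples (log2 scale)\n",
      sep = "")
  cat("  genes:   ", paste(utils::head(genes(object), 4L), collapse = ", "),
      if (d[1L] > 4L) ", ..." else "", "\n", sep = "")
  cat("  samples: ", paste(utils::head(sampleIDs(object), 4L), collapse = ", "),
      if (d[2L] > 4L) ", ..." else "", "\n", sep = "")
})

# ---- CentroidTable ----------------------------------------------------------

#' Subtype centroid table (genes x classes)
#'
#' Prototype expression profile of each subtype class, e.g. the published
#' PAM50 centroids. Centroids are inputs to classification, never trained
#' here. Class column order is preserved as supplied; the canonical
#' (tie-break) order used during classification is alphabetical.
#'
#' @slot values numeric matrix, genes x classes, complete dimnames, >= 2
#'   classes.
#' @export
setClass("CentroidTable", representation(values = "matrix"))

.validCentroidTable <- function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "gene and class identifiers (dimnames) are required")
  else {
    if (ncol(v) < 2L) msg <- c(msg, "a centroid table needs at least 2 classes")
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, paste0("duplicate gene identifier: ",
                           rownames(v)[duplicated(rownames(v))][1L]))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, paste0("duplicate class name: ",
                           colnames(v)[duplicated(colnames(v))][1L]))
  }
  if (is.numeric(v) && !all(is.finite(v)))
    msg <- c(msg, "all centroid values must be finite")
  if (length(msg)) msg else TRUE
}
setValidity("CentroidTable", .validCentroidTable)

#' Construct a CentroidTable
#'
#' @param values numeric matrix (genes x classes) with dimnames; gene symbols
#'   upper-cased on construction.
#' @return a validated [CentroidTable-class].
#' @export
CentroidTable <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- toupper(rownames(values))
  new("CentroidTable", values = values)
}

#' @rdname genes
#' @export
setMethod("genes", "CentroidTable", function(x) rownames(x@values))

#' @rdname classNames
#' @export
setMethod("classNames", "CentroidTable", function(x) colnames(x@values))

#' @rdname exprValues
#' @export
setMethod("exprValues", "CentroidTable", function(x) x@values)

setMethod("show", "CentroidTable", function(object) {
  cat("CentroidTable: ", nrow(object@values), " genes x ",
      ncol(object@values), " classes\n", sep = "")
  cat("  classes: ", paste(classNames(object), collapse = ", "), "\n", sep = "")
})

# ---- ReferenceProfile -------------------------------------------------------

#' Reference expression profile
#'
#' One log2-scale value per gene; the subtraction target of Log2ratio
#' centering. Built either as a per-gene median over an ER-stratified sample
#' subset ([buildMedianReference]) or as an average of within-class averages
#' ([buildAwcaReference]).
#'
#' @slot values named numeric vector (names = upper-cased gene symbols).
#' @slot method character, construction record ("median", "awca" or
#'   "external").
#' @export
setClass("ReferenceProfile",
         representation(values = "numeric", method = "character"))

.validReferenceProfile <- function(object) {
  v <- object@values
  msg <- character()
  if (is.null(names(v))) msg <- c(msg, "reference values must be gene-named")
  else if (anyDuplicated(names(v)))
    msg <- c(msg, paste0("duplicate gene identifier: ",
                         names(v)[duplicated(names(v))][1L]))
  if (!all(is.finite(v))) msg <- c(msg, "all reference values must be finite")
  if (length(msg)) msg else TRUE
}
setValidity("ReferenceProfile", .validReferenceProfile)

#' Construct a ReferenceProfile
#'
#' @param values named numeric vector of per-gene log2 reference values.
#' @param method construction record string.
#' @return a validated [ReferenceProfile-class].
#' @export
ReferenceProfile <- function(values, method = "external") {
  v <- stats::setNames(as.numeric(values), toupper(names(values)))
  new("ReferenceProfile", values = v, method = as.character(method)[1L])
}

#' @rdname genes
#' @export
setMethod("genes", "ReferenceProfile", function(x) names(x@values))

#' Numeric values of a reference profile
#'
#' @param x a `ReferenceProfile`.
#' @return named numeric vector.
#' @export
refValues <- function(x) {
  stopifnot(is(x, "ReferenceProfile"))
  x@values
}

setMethod("show", "ReferenceProfile", function(object) {
  cat("ReferenceProfile (", object@method, "): ", length(object@values),
      " genes\n", sep = "")
})

# ---- SubtypeCallSet ---------------------------------------------------------

#' A set of per-sample subtype calls
#'
#' Per sample: the called class (or `"UNCLASSIFIABLE"`) and the per-class
#' score vector -- rank correlations for the nearest-centroid caller, softmax
#' membership probabilities for the logistic-regression caller (the
#' `scoreType` slot records which). Excluded classes carry `NA` scores.
#'
#' @slot call named character vector, sample id -> class.
#' @slot scores numeric matrix samples x classes.
#' @slot scoreType `"correlation"` or `"membership"`.
#' @slot reasons named character; per-sample reason for UNCLASSIFIABLE calls.
#' @export
setClass("SubtypeCallSet",
         representation(call = "character", scores = "matrix",
                        scoreType = "character", reasons = "character"))

.validSubtypeCallSet <- function(object) {
  msg <- character()
  if (is.null(names(object@call))) msg <- c(msg, "calls must be sample-named")
  if (!identical(names(object@call), rownames(object@scores)))
    msg <- c(msg, "call names must match score matrix rows")
  if (is.null(colnames(object@scores)))
    msg <- c(msg, "score matrix must have class column names")
  ok <- !is.na(object@call) & object@call != "UNCLASSIFIABLE"
  if (any(ok & !(object@call %in% c(colnames(object@scores), NA))))
    msg <- c(msg, "called classes must appear among score columns")
  if (length(msg)) msg else TRUE
}
setValidity("SubtypeCallSet", .validSubtypeCallSet)

#' Construct a SubtypeCallSet
#'
#' @param call named character vector (sample id -> class or
#'   "UNCLASSIFIABLE").
#' @param scores numeric matrix samples x classes (rownames = sample ids).
#' @param scoreType "correlation" or "membership".
#' @param reasons optional named character with per-sample failure reasons.
#' @return a validated [SubtypeCallSet-class].
#' @export
SubtypeCallSet <- function(call, scores, scoreType = "correlation",
                           reasons = character()) {
  new("SubtypeCallSet", call = call, scores = scores,
      scoreType = scoreType, reasons = reasons)
}

#' @rdname calls
#' @export
setMethod("calls", "SubtypeCallSet", function(x) x@call)

#' @rdname calls
#' @export
setMethod("calls", "character", function(x) {
  if (is.null(names(x))) stop("a bare call vector must be sample-named")
  x
})

#' @rdname callScores
#' @export
setMethod("callScores", "SubtypeCallSet", function(x) x@scores)

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "SubtypeCallSet", function(x) names(x@call))

#' @rdname classNames
#' @export
setMethod("classNames", "SubtypeCallSet", function(x) colnames(x@scores))

#' Coerce a SubtypeCallSet to a data.frame
#'
#' @param x SubtypeCallSet
#' @param row.names,optional,... passed for generic compatibility; unused.
#' @return data.frame with sample_id, call, and one score column per class.
#' @export
as.data.frame.SubtypeCallSet <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(sample_id = names(x@call), call = unname(x@call),
             x@scores, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

setMethod("show", "SubtypeCallSet", function(object) {
  tab <- table(object@call)
  cat("SubtypeCallSet: ", length(object@call), " samples (",
      object@scoreType, " scores)\n", sep = "")
  cat("  calls: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
})

# ---- MLRModel ---------------------------------------------------------------

#' Elastic-net multiclass logistic regression model
#'
#' Fitted softmax regression with lasso (l1) and ridge (l2) penalties on the
#' weights (intercepts unpenalized), trained on per-gene z-scored features.
#' The standardization statistics fitted on the training data are stored and
#' re-applied verbatim at prediction time, so the model is a genuine
#' single-sample classifier.
#'
#' @slot classes ordered class names (K).
#' @slot featureGenes ordered gene symbols (G).
#' @slot weights K x G numeric matrix.
#' @slot intercepts length-K numeric.
#' @slot center,scale per-gene standardization statistics (length G;
#'   scale epsilon-floored, strictly positive).
#' @slot l1,l2 non-negative penalty strengths.
#' @slot fitMeta list: seed, iterations, objective, converged.
#' @export
setClass("MLRModel",
         representation(classes = "character", featureGenes = "character",
                        weights = "matrix", intercepts = "numeric",
                        center = "numeric", scale = "numeric",
                        l1 = "numeric", l2 = "numeric", fitMeta = "list"))

.validMLRModel <- function(object) {
  msg <- character()
  K <- length(object@classes); G <- length(object@featureGenes)
  if (K < 2L) msg <- c(msg, "need >= 2 classes")
  if (!identical(dim(object@weights), c(K, G)))
    msg <- c(msg, "weights must be K x G")
  if (length(object@intercepts) != K)
    msg <- c(msg, "intercepts must have length K")
  if (length(object@center) != G || length(object@scale) != G)
    msg <- c(msg, "standardization statistics must have length G")
  if (length(object@scale) && any(object@scale <= 0))
    msg <- c(msg, "standardization scale must be strictly positive")
  if (object@l1 < 0 || object@l2 < 0)
    msg <- c(msg, "penalties must be non-negative")
  if (length(msg)) msg else TRUE
}
setValidity("MLRModel", .validMLRModel)

#' @rdname classNames
#' @export
setMethod("classNames", "MLRModel", function(x) x@classes)

#' @rdname genes
#' @export
setMethod("genes", "MLRModel", function(x) x@featureGenes)

#' Weight matrix of a fitted MLR model
#'
#' @param model an `MLRModel`.
#' @return K x G numeric matrix (classes x genes).
#' @export
modelWeights <- function(model) {
  stopifnot(is(model, "MLRModel"))
  model@weights
}

setMethod("show", "MLRModel", function(object) {
  nz <- sum(abs(object@weights) > 1e-8)
  cat("MLRModel: ", length(object@classes), " classes x ",
      length(object@featureGenes), " genes; l1=", object@l1,
      ", l2=", object@l2, "; ", nz, " non-zero weights\n", sep = "")
})

# ---- RORModel ---------------------------------------------------------------

#' Risk-of-recurrence scoring model
#'
#' The ROR score is a weighted sum of per-class centroid correlations plus a
#' tumor-size term, optionally affinely rescaled, then binned into
#' low/intermediate/high risk groups. Coefficients and thresholds are always
#' supplied by the user (e.g. transcribed from published Cox-model
#' coefficients); the package ships only a clearly labelled placeholder
#' configuration.
#'
#' @slot classWeights named numeric, class -> weight.
#' @slot tumorSizeWeight numeric scalar.
#' @slot thresholds length-2 increasing numeric: (low/intermediate,
#'   intermediate/high) boundaries. Boundary values fall in the lower group.
#' @slot rescale length-2 numeric (a, b); applied as a * raw + b.
#' @export
setClass("RORModel",
         representation(classWeights = "numeric", tumorSizeWeight = "numeric",
                        thresholds = "numeric", rescale = "numeric"))

.validRORModel <- function(object) {
  msg <- character()
  if (is.null(names(object@classWeights)))
    msg <- c(msg, "class weights must be class-named")
  if (length(object@thresholds) != 2L ||
      !(object@thresholds[1L] < object@thresholds[2L]))
    msg <- c(msg, "thresholds must be two strictly increasing values")
  if (length(object@rescale) != 2L)
    msg <- c(msg, "rescale must be (a, b)")
  if (length(msg)) msg else TRUE
}
setValidity("RORModel", .validRORModel)

#' Construct a RORModel
#'
#' @param classWeights named numeric vector of per-class correlation weights.
#' @param tumorSizeWeight weight of the tumor-size covariate (default 0).
#' @param thresholds increasing pair (low/intermediate, intermediate/high).
#' @param rescale affine rescaling (a, b), applied as `a * raw + b`
#'   (default identity).
#' @return a validated [RORModel-class].
#' @export
RORModel <- function(classWeights, tumorSizeWeight = 0,
                     thresholds = c(0, 1), rescale = c(1, 0)) {
  new("RORModel", classWeights = classWeights,
      tumorSizeWeight = as.numeric(tumorSizeWeight)[1L],
      thresholds = as.numeric(thresholds), rescale = as.numeric(rescale))
}

setMethod("show", "RORModel", function(object) {
  cat("RORModel: weights on ", paste(names(object@classWeights),
      collapse = ", "), "; tumor-size weight ", object@tumorSizeWeight,
      "; thresholds (", object@thresholds[1L], ", ", object@thresholds[2L],
      ")\n", sep = "")
})
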