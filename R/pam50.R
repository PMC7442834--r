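# Log2ratio centering and nearest-centroid subtype calling. Everything here
# is strictly per-sample: no statistic is ever computed across the sample set
# being classified, which is what makes the single-sample == batch contract
# exact.

#' Center an expression matrix against a reference profile
#'
#' Realizes Log2ratio centering: both inputs are log2-scale, so the Log2ratio
#' of sample vs reference is the per-gene subtraction
#' `expr[g, s] - ref[g]`. Operates on the gene intersection of matrix and
#' reference (optionally restricted to, and ordered by, a supplied gene set,
#' typically the centroid genes).
#'
#' @param expr an [ExpressionMatrix-class] (log2 scale).
#' @param ref a [ReferenceProfile-class] (log2 scale).
#' @param geneSet optional character vector (e.g. `genes(centroids)`): the
#'   output is restricted to this set and ordered by it.
#' @param minOverlap minimum fraction of `geneSet` that must survive the
#'   intersection (default 0.8); violations raise an error naming the
#'   missing genes.
#' @return a centered [ExpressionMatrix-class].
#' @export
centerAgainstReference <- function(expr, ref, geneSet = NULL,
                                   minOverlap = 0.8) {
  stopifnot(is(expr, "ExpressionMatrix"), is(ref, "ReferenceProfile"))
  common <- intersect(genes(expr), genes(ref))
  if (!is.null(geneSet)) {
    geneSet <- toupper(geneSet)
    keep <- geneSet[geneSet %in% common]
    if (length(keep) < minOverlap * length(geneSet)) {
      miss <- setdiff(geneSet, common)
      stop("only ", length(keep), "/", length(geneSet),
           " classification genes present in both matrix and reference ",
           "(minimum overlap ", minOverlap, "); missing: ",
           paste(utils::head(miss, 10L), collapse = ", "),
           if (length(miss) > 10L) ", ..." else "")
    }
    common <- keep
  }
  if (!length(common))
    stop("empty gene intersection between expression matrix and reference")
  v <- exprValues(expr)[common, , drop = FALSE] - refValues(ref)[common]
  ExpressionMatrix(v)
}

#' Spearman rank correlation
#'
#' Spearman's rho with average (fractional) rank handling for ties: both
#' vectors are rank-transformed, then Pearson-correlated.
#'
#' @param x,y numeric vectors of equal length >= 3, each with at least two
#'   distinct values.
#' @return rho in `[-1, 1]`.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: constant vector")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# Correlation of each sample column against each centroid column, computed
# per sample so batch composition can never leak in. Constant sample columns
# yield an NA row (handled upstream as UNCLASSIFIABLE).
.corToCentroids <- function(sampleMat, centroidMat, metric) {
  if (metric == "spearman") {
    sampleMat <- .rankColumns(sampleMat)
    centroidMat <- .rankColumns(centroidMat)
  }
  constant <- apply(sampleMat, 2L, function(v) length(unique(v)) < 2L)
  out <- matrix(NA_real_, ncol(sampleMat), ncol(centroidMat),
                dimnames = list(colnames(sampleMat), colnames(centroidMat)))
  if (any(!constant))
    out[!constant, ] <- t(stats::cor(centroidMat,
                                     sampleMat[, !constant, drop = FALSE]))
  out
}

#' Nearest-centroid subtype classification
#'
#' Per sample: correlation of the centered profile with every non-excluded
#' class centroid, over the genes common to matrix and centroid table; the
#' call is the class of maximal correlation, ties broken by the canonical
#' (alphabetical) class order. A constant centered profile has no defined
#' rank correlation and is called `UNCLASSIFIABLE` with the reason recorded.
#'
#' @param centered a centered [ExpressionMatrix-class] (see
#'   [centerAgainstReference]).
#' @param centroids a [CentroidTable-class].
#' @param metric `"spearman"` (default, the standard PAM50 similarity) or
#'   `"pearson"` (the Prosigna-style variant, typically combined with
#'   excluding the Normal-like class).
#' @param excludedClasses classes dropped from the comparison (at least two
#'   classes must remain); their score columns are `NA`.
#' @return a [SubtypeCallSet-class] with correlation scores.
#' @export
classifySubtypes <- function(centered, centroids,
                             metric = c("spearman", "pearson"),
                             excludedClasses = character()) {
  stopifnot(is(centered, "ExpressionMatrix"), is(centroids, "CentroidTable"))
  metric <- match.arg(metric)
  allClasses <- classNames(centroids)
  bad <- setdiff(excludedClasses, allClasses)
  if (length(bad))
    stop("excluded class not in centroid table: ", paste(bad, collapse = ", "))
  keep <- setdiff(allClasses, excludedClasses)
  if (length(keep) < 2L)
    stop("excluding ", paste(excludedClasses, collapse = ", "),
         " leaves fewer than 2 classes")
  common <- intersect(genes(centroids), genes(centered))
  if (length(common) < 3L)
    stop("fewer than 3 genes shared between matrix and centroids")
  sm <- exprValues(centered)[common, , drop = FALSE]
  cm <- exprValues(centroids)[common, keep, drop = FALSE]
  rho <- .corToCentroids(sm, cm, metric)
  scores <- matrix(NA_real_, nrow(rho), length(allClasses),
                   dimnames = list(rownames(rho), allClasses))
  scores[, keep] <- rho
  call <- vapply(seq_len(nrow(scores)), function(i)
    .argmaxCanonical(scores[i, ]), character(1L))
  reasons <- character()
  failed <- is.na(call)
  if (any(failed)) {
    call[failed] <- "UNCLASSIFIABLE"
    reasons <- stats::setNames(
      rep("constant centered profile: rank correlation undefined",
          sum(failed)), rownames(scores)[failed])
  }
  SubtypeCallSet(stats::setNames(call, rownames(scores)), scores,
                 scoreType = "correlation", reasons = reasons)
}

#' Single-sample subtype classification against a fixed reference
#'
#' Centers one profile against a fixed (typically external, AWCA-built)
#' reference and classifies it. Because centering and correlation are
#' computed per sample against fixed inputs, the result is exactly identical
#' to classifying the same sample inside any batch with the same reference
#' and centroids.
#'
#' @param profile a one-sample [ExpressionMatrix-class] (log2 scale,
#'   uncentered).
#' @param ref a fixed [ReferenceProfile-class].
#' @param centroids a [CentroidTable-class].
#' @param metric,excludedClasses,minOverlap as in [classifySubtypes] /
#'   [centerAgainstReference].
#' @return a one-sample [SubtypeCallSet-class].
#' @export
classifySingleSample <- function(profile, ref, centroids,
                                 metric = c("spearman", "pearson"),
                                 excludedClasses = character(),
                                 minOverlap = 0.8) {
  stopifnot(is(profile, "ExpressionMatrix"))
  if (ncol(exprValues(profile)) != 1L)
    stop("classifySingleSample expects exactly one sample, got ",
         ncol(exprValues(profile)))
  centered <- centerAgainstReference(profile, ref, geneSet = genes(centroids),
                                     minOverlap = minOverlap)
  classifySubtypes(centered, centroids, metric = metric,
                   excludedClasses = excludedClasses)
}
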