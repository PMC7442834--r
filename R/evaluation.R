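# Comparison instruments: concordance, Cohen's kappa, confusion matrices
# with macro-averaged recall/precision, and pairwise concordance
# distributions. Call sets are always matched by sample id, never by
# position; UNCLASSIFIABLE pairs are excluded from agreement statistics and
# counted.

# Align two call vectors on their common sample ids and drop pairs where
# either side is UNCLASSIFIABLE / NA.
.alignCalls <- function(a, b) {
  a <- .callVector(a); b <- .callVector(b)
  common <- intersect(names(a), names(b))
  if (!length(common))
    stop("no common sample ids between the two call sets")
  a <- a[common]; b <- b[common]
  bad <- is.na(a) | is.na(b) | a == "UNCLASSIFIABLE" | b == "UNCLASSIFIABLE"
  list(a = a[!bad], b = b[!bad], excluded = sum(bad))
}

#' Concordance between two call sets
#'
#' `100 * matching / compared`, over the samples present in both sets and
#' classifiable in both. The number of excluded (unclassifiable) pairs is
#' reported as an attribute.
#'
#' @param a,b [SubtypeCallSet-class]s or sample-named character vectors.
#' @return percent concordance (numeric), with attributes `n_compared` and
#'   `n_excluded`.
#' @export
concordance <- function(a, b) {
  al <- .alignCalls(a, b)
  if (!length(al$a))
    stop("no classifiable sample pairs to compare")
  structure(100 * mean(al$a == al$b),
            n_compared = length(al$a), n_excluded = al$excluded)
}

#' Cohen's kappa between two call sets
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the marginal products of the contingency
#' table. When both sets are constant and equal (`p_e = 1`), kappa is 1 if
#' the observed agreement is perfect and an error otherwise.
#'
#' @inheritParams concordance
#' @return kappa in `[-1, 1]`.
#' @export
cohensKappa <- function(a, b) {
  al <- .alignCalls(a, b)
  if (!length(al$a)) stop("no classifiable sample pairs to compare")
  lev <- sort(unique(c(al$a, al$b)))
  tab <- table(factor(al$a, lev), factor(al$b, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1 - 1e-12) {
    if (po >= 1 - 1e-12) return(1)
    stop("kappa undefined: expected agreement is 1 but observed is not")
  }
  (po - pe) / (1 - pe)
}

#' Confusion matrix with per-class and macro-averaged recall/precision
#'
#' Rows are truth, columns predictions. `recall_k = diag_k / rowsum_k`,
#' `precision_k = diag_k / colsum_k`; the macro averages are unweighted
#' means over the classes with non-zero denominators (classes excluded from
#' an average are reported).
#'
#' @param truth,pred call sets or sample-named label vectors (matched by
#'   id).
#' @param classes class vocabulary; defaults to the union of observed
#'   labels, canonically ordered.
#' @return list: `confusion` (K x K integer matrix), `recall`, `precision`
#'   (named, NA where undefined), `macroRecall`, `macroPrecision`,
#'   `excludedFromRecall`, `excludedFromPrecision`, `nExcludedPairs`.
#' @export
confusionAndMacro <- function(truth, pred, classes = NULL) {
  al <- .alignCalls(truth, pred)
  if (is.null(classes))
    classes <- .canonicalOrder(unique(c(al$a, al$b)))
  bad <- setdiff(unique(c(al$a, al$b)), classes)
  if (length(bad))
    stop("label(s) outside the class vocabulary: ",
         paste(bad, collapse = ", "))
  tab <- table(factor(al$a, classes), factor(al$b, classes))
  cm <- matrix(as.integer(tab), nrow(tab), dimnames = dimnames(tab))
  rs <- rowSums(cm); cs <- colSums(cm); dg <- diag(cm)
  recall <- ifelse(rs > 0, dg / rs, NA_real_)
  precision <- ifelse(cs > 0, dg / cs, NA_real_)
  names(recall) <- names(precision) <- classes
  list(confusion = cm, recall = recall, precision = precision,
       macroRecall = mean(recall, na.rm = TRUE),
       macroPrecision = mean(precision, na.rm = TRUE),
       excludedFromRecall = classes[is.na(recall)],
       excludedFromPrecision = classes[is.na(precision)],
       nExcludedPairs = al$excluded)
}

#' Pairwise concordance distribution over several call sets
#'
#' Concordance over all C(m, 2) pairs of call sets on a common sample set;
#' summarized by mean and sample standard deviation (a single pair has sd 0
#' by convention, flagged by `degenerate = TRUE`).
#'
#' @param callSets list of >= 2 call sets (SubtypeCallSet or named
#'   character).
#' @return list: `values` (all pairwise concordances, %), `pairs` (index
#'   pairs), `mean`, `sd`, `degenerate`.
#' @export
pairwiseConcordanceDistribution <- function(callSets) {
  m <- length(callSets)
  if (m < 2L) stop("need at least 2 call sets")
  pr <- utils::combn(m, 2L)
  vals <- apply(pr, 2L, function(ij)
    as.numeric(concordance(callSets[[ij[1L]]], callSets[[ij[2L]]])))
  list(values = vals, pairs = t(pr), mean = mean(vals),
       sd = if (length(vals) > 1L) stats::sd(vals) else 0,
       degenerate = length(vals) < 2L)
}
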