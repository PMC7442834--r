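# Reference-profile construction: the ER-stratified median reference of the
# standard PAM50 workflow, the AWCA (average of within-class averages)
# double-averaging reference, the one-round AWCA pipeline, and the
# subset-size-halving stability experiment.

#' Sample an ER-stratified subset of a cohort
#'
#' Draws, without replacement and reproducibly from `seed`, a subset with a
#' fixed proportion of ER-positive cases (the 60/40 ER+/ER- convention of
#' reference construction). ER+ quota = round-half-up of
#' `size * erPosFraction`; the remainder is ER-. Samples with UNKNOWN ER
#' status are ineligible.
#'
#' @param annotations data.frame as from [loadAnnotations] (columns
#'   sample_id, er_status).
#' @param size subset size.
#' @param erPosFraction fraction of ER+ cases, in (0, 1); default 0.6.
#' @param seed integer seed.
#' @return character vector of sample ids (ER+ block first).
#' @export
sampleERStratifiedSubset <- function(annotations, size, erPosFraction = 0.6,
                                     seed = 1L) {
  stopifnot(size >= 1L, erPosFraction > 0, erPosFraction < 1)
  pos <- annotations$sample_id[annotations$er_status == "POS"]
  neg <- annotations$sample_id[annotations$er_status == "NEG"]
  nPos <- floor(size * erPosFraction + 0.5)
  nNeg <- size - nPos
  if (length(pos) < nPos)
    stop("insufficient ER+ samples: need ", nPos, ", have ", length(pos),
         " (shortfall ", nPos - length(pos), ")")
  if (length(neg) < nNeg)
    stop("insufficient ER- samples: need ", nNeg, ", have ", length(neg),
         " (shortfall ", nNeg - length(neg), ")")
  .withSeed(seed, c(sample(pos, nPos), sample(neg, nNeg)))
}

#' Median reference profile
#'
#' Per gene, the median expression across a sample subset (even counts use
#' the mean of the two middle values). This is the standard PAM50 reference;
#' it depends on the subset's subtype composition, which is exactly the
#' instability the AWCA reference removes.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param subset character vector of sample ids (all must be present).
#' @return a [ReferenceProfile-class] with method "median".
#' @export
buildMedianReference <- function(expr, subset) {
  stopifnot(is(expr, "ExpressionMatrix"), length(subset) >= 1L)
  missing <- setdiff(subset, sampleIDs(expr))
  if (length(missing))
    stop("unknown sample id(s): ", paste(utils::head(missing, 5L),
                                         collapse = ", "))
  v <- exprValues(expr)[, subset, drop = FALSE]
  ReferenceProfile(apply(v, 1L, stats::median), method = "median")
}

#' AWCA reference profile (average of within-class averages)
#'
#' Double averaging: per gene, first the mean expression within each called
#' subtype class, then the unweighted mean of those within-class means over
#' the retained classes. The result is exactly invariant to the number of
#' samples per class (duplicating samples within a class changes nothing),
#' which makes the reference robust to cohort composition. Classes that are
#' explicitly excluded, or whose called sample count falls below
#' `minClassSize` (auto-exclusion, reported via message), are dropped from
#' the outer average -- mirroring the exclusion of an undersized Normal-like
#' class.
#'
#' @param expr an [ExpressionMatrix-class] covering the called samples.
#' @param callSet a [SubtypeCallSet-class] or sample-named character vector
#'   of class labels (UNCLASSIFIABLE samples are ignored).
#' @param excludedClasses classes to drop from the outer average.
#' @param minClassSize minimum called samples for a class to enter the outer
#'   average (default 10).
#' @return a [ReferenceProfile-class] with method "awca".
#' @export
buildAwcaReference <- function(expr, callSet, excludedClasses = character(),
                               minClassSize = 10L) {
  stopifnot(is(expr, "ExpressionMatrix"))
  cl <- .callVector(callSet)
  cl <- cl[names(cl) %in% sampleIDs(expr)]
  cl <- cl[!is.na(cl) & cl != "UNCLASSIFIABLE"]
  sizes <- table(cl)
  retained <- setdiff(names(sizes)[sizes >= minClassSize], excludedClasses)
  if (length(retained) < 2L)
    stop("AWCA needs >= 2 retained classes; class sizes: ",
         paste(names(sizes), as.integer(sizes), sep = "=", collapse = ", "),
         "; excluded: ", paste(excludedClasses, collapse = ", "))
  dropped <- setdiff(names(sizes), c(retained, excludedClasses))
  if (length(dropped))
    message("AWCA auto-excluded undersized class(es): ",
            paste(dropped, as.integer(sizes[dropped]), sep = "=",
                  collapse = ", "))
  v <- exprValues(expr)
  classMeans <- vapply(retained, function(k)
    rowMeans(v[, names(cl)[cl == k], drop = FALSE]), numeric(nrow(v)))
  ReferenceProfile(rowMeans(classMeans), method = "awca")
}

#' One-round AWCA classification pipeline
#'
#' The full robust-subtyping procedure: (1) draw an ER-stratified subset and
#' build a median reference from it (or accept precomputed labels and skip
#' this step); (2) classify the whole cohort against that reference
#' (preliminary standard PAM50 calls); (3) build the AWCA reference from the
#' preliminary calls over the whole cohort; (4) re-classify the whole cohort
#' against the AWCA reference. Exactly one re-classification round is
#' performed. A warning (not an error) is emitted when the reference subset
#' has fewer than 50 samples, below the recommended minimum for stable
#' references.
#'
#' @param expr an [ExpressionMatrix-class], the whole cohort.
#' @param annotations cohort annotations (needed unless `preliminaryCalls`
#'   is supplied).
#' @param centroids a [CentroidTable-class].
#' @param subsetSize reference-subset size (default 400).
#' @param erPosFraction ER+ fraction of the subset (default 0.6).
#' @param seed integer seed for the subset draw.
#' @param metric correlation metric for both classification rounds.
#' @param excludedClasses classes excluded from the AWCA outer average (and
#'   only there; both classifications use the full class set unless
#'   `classifyExcludedClasses` is given).
#' @param classifyExcludedClasses classes excluded from classification
#'   itself (default none).
#' @param minClassSize AWCA minimum class size (default 10).
#' @param preliminaryCalls optional precomputed labels (SubtypeCallSet or
#'   named character): when given, steps 1-2 are skipped and the AWCA
#'   reference is built directly from them.
#' @param minOverlap minimum centroid-gene overlap for centering.
#' @return list with elements `reference` (the AWCA
#'   [ReferenceProfile-class]), `finalCalls`, `preliminaryCalls`,
#'   `medianReference` (NULL when labels were supplied) and `subset`.
#' @export
awcaPipeline <- function(expr, annotations = NULL, centroids,
                         subsetSize = 400L, erPosFraction = 0.6, seed = 1L,
                         metric = "spearman",
                         excludedClasses = character(),
                         classifyExcludedClasses = character(),
                         minClassSize = 10L, preliminaryCalls = NULL,
                         minOverlap = 0.8) {
  stopifnot(is(expr, "ExpressionMatrix"), is(centroids, "CentroidTable"))
  medianRef <- NULL
  subset <- NULL
  if (is.null(preliminaryCalls)) {
    if (is.null(annotations))
      stop("either annotations or preliminaryCalls must be supplied")
    if (subsetSize < 50L)
      warning("reference subset of ", subsetSize,
              " samples is below the recommended minimum of 50-100")
    subset <- sampleERStratifiedSubset(annotations, subsetSize,
                                       erPosFraction, seed)
    medianRef <- buildMedianReference(expr, subset)
    centered <- centerAgainstReference(expr, medianRef,
                                       geneSet = genes(centroids),
                                       minOverlap = minOverlap)
    preliminaryCalls <- classifySubtypes(centered, centroids, metric = metric,
                                         excludedClasses = classifyExcludedClasses)
  }
  awcaRef <- buildAwcaReference(expr, preliminaryCalls,
                                excludedClasses = excludedClasses,
                                minClassSize = minClassSize)
  centered <- centerAgainstReference(expr, awcaRef,
                                     geneSet = genes(centroids),
                                     minOverlap = minOverlap)
  finalCalls <- classifySubtypes(centered, centroids, metric = metric,
                                 excludedClasses = classifyExcludedClasses)
  list(reference = awcaRef, finalCalls = finalCalls,
       preliminaryCalls = preliminaryCalls, medianReference = medianRef,
       subset = subset)
}

#' Reference-stability experiment (subset-size halving)
#'
#' For each subset size and replicate: draw an ER-stratified subset, build
#' the median reference and classify the whole cohort (the standard
#' strategy); then build the AWCA reference from those calls and re-classify
#' (the AWCA strategy). Records, per strategy and size, the concordance of
#' each replicate with `truthLabels` and all pairwise concordances between
#' replicates -- the instrument behind the observation that AWCA-based calls
#' are both closer to the published labels and far more stable across
#' reference subsets.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param annotations cohort annotations with ER status.
#' @param centroids a [CentroidTable-class].
#' @param sizes integer vector of subset sizes (e.g. halving 400, 200, 100,
#'   50, 25).
#' @param replicates replicates per size (>= 2 for pairwise statistics).
#' @param truthLabels sample-named character vector of reference labels.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param erPosFraction,excludedClasses,minClassSize,metric,minOverlap
#'   forwarded to the pipeline components.
#' @return object of class `StabilityReport`: list with `perReplicate`
#'   (size, strategy, replicate, concordance-with-truth), `pairwise`
#'   (size, strategy, i, j, concordance), `summary` (per size x strategy:
#'   means and standard deviations), and `skipped` (infeasible replicates).
#' @export
stabilityExperiment <- function(expr, annotations, centroids, sizes,
                                replicates = 10L, truthLabels, seed = 1L,
                                erPosFraction = 0.6,
                                excludedClasses = character(),
                                minClassSize = 10L, metric = "spearman",
                                minOverlap = 0.8) {
  stopifnot(replicates >= 1L)
  truthLabels <- .callVector(truthLabels)
  seeds <- matrix(.subSeeds(seed, length(sizes) * replicates),
                  nrow = length(sizes))
  perRep <- list(); pairwise <- list(); skipped <- list()
  for (si in seq_along(sizes)) {
    sz <- sizes[si]
    callsBySt <- list(median = list(), awca = list())
    for (r in seq_len(replicates)) {
      res <- tryCatch(
        suppressWarnings(awcaPipeline(
          expr, annotations, centroids, subsetSize = sz,
          erPosFraction = erPosFraction, seed = seeds[si, r],
          metric = metric, excludedClasses = excludedClasses,
          minClassSize = minClassSize, minOverlap = minOverlap)),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning("size ", sz, " replicate ", r, " skipped: ",
                conditionMessage(res))
        skipped[[length(skipped) + 1L]] <-
          data.frame(size = sz, replicate = r,
                     reason = conditionMessage(res))
        next
      }
      callsBySt$median[[length(callsBySt$median) + 1L]] <- res$preliminaryCalls
      callsBySt$awca[[length(callsBySt$awca) + 1L]] <- res$finalCalls
    }
    for (st in c("median", "awca")) {
      cs <- callsBySt[[st]]
      m <- length(cs)
      if (!m) next
      conc <- vapply(cs, function(x)
        as.numeric(concordance(x, truthLabels)), numeric(1L))
      perRep[[length(perRep) + 1L]] <-
        data.frame(size = sz, strategy = st, replicate = seq_len(m),
                   concordance_truth = conc)
      if (m >= 2L) {
        pr <- utils::combn(m, 2L)
        pw <- apply(pr, 2L, function(ij)
          as.numeric(concordance(cs[[ij[1L]]], cs[[ij[2L]]])))
        pairwise[[length(pairwise) + 1L]] <-
          data.frame(size = sz, strategy = st, i = pr[1L, ], j = pr[2L, ],
                     concordance = pw)
      }
    }
  }
  perRep <- do.call(rbind, perRep)
  pairwise <- if (length(pairwise)) do.call(rbind, pairwise) else
    data.frame(size = integer(), strategy = character(), i = integer(),
               j = integer(), concordance = numeric())
  summ <- do.call(rbind, lapply(split(
    perRep, interaction(perRep$size, perRep$strategy, drop = TRUE)),
    function(d) {
      pw <- pairwise$concordance[pairwise$size == d$size[1L] &
                                 pairwise$strategy == d$strategy[1L]]
      data.frame(size = d$size[1L], strategy = d$strategy[1L],
                 replicates = nrow(d),
                 mean_truth = mean(d$concordance_truth),
                 sd_truth = if (nrow(d) > 1L) stats::sd(d$concordance_truth)
                            else 0,
                 mean_pairwise = if (length(pw)) mean(pw) else NA_real_,
                 sd_pairwise = if (length(pw) > 1L) stats::sd(pw) else
                   if (length(pw) == 1L) 0 else NA_real_)
    }))
  rownames(summ) <- NULL
  structure(list(perReplicate = perRep, pairwise = pairwise, summary = summ,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else
                   NULL),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat("StabilityReport (values in %):\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$skipped))
    cat(nrow(x$skipped), "replicate(s) skipped (infeasible strata)\n")
  invisible(x)
}
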