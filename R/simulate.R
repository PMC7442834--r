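# Synthetic cohort generator: class-specific centroid profiles on the log2
# scale, independent Gaussian per-gene noise, per-class ER-status
# probabilities, ambiguous mixture samples, planted pairwise DE genes, and
# the balanced training-split constructor. Everything is reproducible from
# the config seed.

#' Simulation configuration
#'
#' Defaults describe the documented demo cohort: 1,000 genes of which the
#' first 100 are class-informative (the simulated analogue of a
#' classification panel), five subtype classes sized 120/100/60/50/20,
#' per-class ER+ probabilities echoing the luminal-ER association, unit
#' log2-scale Gaussian noise, and 10% ambiguous samples drawn from an even
#' two-class centroid mixture.
#'
#' @param nGenes total genes.
#' @param classSizes named integer vector: per-class sample counts.
#' @param nInformative number of class-informative genes (the first
#'   `nInformative` gene indices).
#' @param centroidSeparation sd of the per-class centroid offsets on
#'   informative genes (log2 units).
#' @param noiseSd per-gene Gaussian noise sd (log2 units).
#' @param ambiguousFraction fraction of each class's samples drawn from a
#'   two-class centroid mixture, in `[0, 1)`.
#' @param lambda mixture weight of the own-class centroid for ambiguous
#'   samples, in (0, 1).
#' @param erPosProb named per-class probability of ER-positive status.
#' @param tumorSizeMeanlog,tumorSizeSdlog log-normal tumor-size (cm)
#'   parameters.
#' @param seed integer seed.
#' @return object of class `SimulationConfig`.
#' @export
simulationConfig <- function(nGenes = 1000L,
                             classSizes = c(LumA = 120L, LumB = 100L,
                                            Basal = 60L, Her2 = 50L,
                                            Normal = 20L),
                             nInformative = 100L,
                             centroidSeparation = 1,
                             noiseSd = 1,
                             ambiguousFraction = 0.1,
                             lambda = 0.5,
                             erPosProb = c(LumA = 0.95, LumB = 0.9,
                                           Basal = 0.1, Her2 = 0.4,
                                           Normal = 0.7),
                             tumorSizeMeanlog = log(2),
                             tumorSizeSdlog = 0.4,
                             seed = 1L) {
  stopifnot(nGenes >= 1L, all(classSizes >= 1L),
            !is.null(names(classSizes)), nInformative <= nGenes,
            ambiguousFraction >= 0, ambiguousFraction < 1,
            lambda > 0, lambda < 1,
            all(names(classSizes) %in% names(erPosProb)))
  structure(list(nGenes = as.integer(nGenes),
                 classSizes = classSizes,
                 nInformative = as.integer(nInformative),
                 centroidSeparation = centroidSeparation,
                 noiseSd = noiseSd,
                 ambiguousFraction = ambiguousFraction,
                 lambda = lambda,
                 erPosProb = erPosProb[names(classSizes)],
                 tumorSizeMeanlog = tumorSizeMeanlog,
                 tumorSizeSdlog = tumorSizeSdlog,
                 seed = as.integer(seed),
                 deSpec = list()),
            class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig: ", x$nGenes, " genes (", x$nInformative,
      " informative), classes ",
      paste(names(x$classSizes), x$classSizes, sep = "=", collapse = ", "),
      "; noise sd ", x$noiseSd, "; ambiguous ",
      100 * x$ambiguousFraction, "%\n", sep = "")
  if (length(x$deSpec))
    cat("  planted DE: ", length(x$deSpec), " pair set(s)\n", sep = "")
  invisible(x)
}

#' Plant pairwise differentially expressed genes in a config
#'
#' Reserves disjoint blocks of non-informative genes and shifts their
#' centroid values between the two classes of each named pair
#' (`+shift/2` in the first, `-shift/2` in the second; all other classes
#' stay at baseline), so the planted genes differ in mean between the named
#' pair. Ground truth is recorded in the config and surfaces in the
#' simulated cohort's `plantedDeGenes`.
#'
#' @param config a `SimulationConfig`.
#' @param pairs list of length-2 character vectors of class names (a pair
#'   may be planted at most once).
#' @param genesPerPair genes reserved per pair.
#' @param shift mean difference between the pair (log2 units; 0 plants a
#'   statistically null negative-control set).
#' @return the augmented `SimulationConfig`.
#' @export
plantPairwiseDE <- function(config, pairs, genesPerPair, shift) {
  stopifnot(inherits(config, "SimulationConfig"), genesPerPair >= 1L)
  existing <- vapply(config$deSpec, function(d)
    paste(sort(d$pair), collapse = "|"), character(1L))
  used <- sum(vapply(config$deSpec, function(d) length(d$genes), integer(1L)))
  nextFree <- config$nInformative + used + 1L
  for (p in pairs) {
    stopifnot(length(p) == 2L, all(p %in% names(config$classSizes)))
    key <- paste(sort(p), collapse = "|")
    if (key %in% existing)
      stop("overlapping assignment: pair ", key, " already has planted genes")
    existing <- c(existing, key)
    if (nextFree + genesPerPair - 1L > config$nGenes)
      stop("not enough spare (non-informative) genes to plant ",
           genesPerPair, " genes for pair ", key)
    config$deSpec[[length(config$deSpec) + 1L]] <-
      list(pair = p, genes = seq.int(nextFree, length.out = genesPerPair),
           shift = shift)
    nextFree <- nextFree + genesPerPair
  }
  config
}

.geneNames <- function(n) sprintf("G%04d", seq_len(n))
.sampleNames <- function(n) sprintf("S%04d", seq_len(n))

#' Simulate a cohort
#'
#' Gene `g` of a sample in class `k` is drawn as
#' `centroid[g, k] + Normal(0, noiseSd)`. Centroids share a common baseline
#' (`Normal(8, 2)` log2 units); informative genes additionally receive
#' independent per-class offsets `Normal(0, centroidSeparation)`, and
#' planted DE genes the configured pair shifts. A configured fraction of
#' each class's samples is ambiguous: its mean profile is
#' `lambda * centroid_k + (1 - lambda) * centroid_j` for a recorded partner
#' class `j`. ER status and tumor size are sampled per class. Fully
#' reproducible from the config seed.
#'
#' @param config a `SimulationConfig`.
#' @return object of class `SimulatedCohort`: `expression`
#'   ([ExpressionMatrix-class]), `trueLabels` (named character),
#'   `annotations` (data.frame), `plantedCentroids`
#'   ([CentroidTable-class], all genes), `panel` (informative gene names),
#'   `plantedDeGenes` (named list, pair -> gene names), `ambiguousPairs`
#'   (data.frame sample_id, own class, partner), `config`.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  K <- length(config$classSizes)
  classes <- names(config$classSizes)
  gn <- .geneNames(config$nGenes)
  .withSeed(config$seed, {
    base <- stats::rnorm(config$nGenes, mean = 8, sd = 2)
    centroids <- matrix(base, config$nGenes, K,
                        dimnames = list(gn, classes))
    if (config$nInformative > 0L) {
      idx <- seq_len(config$nInformative)
      centroids[idx, ] <- centroids[idx, ] +
        matrix(stats::rnorm(config$nInformative * K,
                            sd = config$centroidSeparation),
               config$nInformative, K)
    }
    for (d in config$deSpec) {
      centroids[d$genes, d$pair[1L]] <- centroids[d$genes, d$pair[1L]] +
        d$shift / 2
      centroids[d$genes, d$pair[2L]] <- centroids[d$genes, d$pair[2L]] -
        d$shift / 2
    }
    n <- sum(config$classSizes)
    sn <- .sampleNames(n)
    labels <- stats::setNames(rep(classes, config$classSizes), sn)
    meanProfiles <- centroids[, labels, drop = FALSE]
    colnames(meanProfiles) <- sn
    ambiguous <- data.frame(sample_id = character(), class = character(),
                            partner = character(), stringsAsFactors = FALSE)
    if (config$ambiguousFraction > 0 && K >= 2L) {
      for (k in classes) {
        ids <- sn[labels == k]
        nAmb <- round(config$ambiguousFraction * length(ids))
        if (nAmb < 1L) next
        ambIds <- sample(ids, nAmb)
        partners <- sample(setdiff(classes, k), nAmb, replace = TRUE)
        meanProfiles[, ambIds] <-
          config$lambda * centroids[, rep(k, nAmb)] +
          (1 - config$lambda) * centroids[, partners]
        ambiguous <- rbind(ambiguous,
                           data.frame(sample_id = ambIds, class = k,
                                      partner = partners,
                                      stringsAsFactors = FALSE))
      }
    }
    values <- meanProfiles +
      matrix(stats::rnorm(config$nGenes * n, sd = config$noiseSd),
             config$nGenes, n)
    colnames(values) <- sn
    er <- ifelse(stats::runif(n) < config$erPosProb[labels], "POS", "NEG")
    size <- stats::rlnorm(n, config$tumorSizeMeanlog, config$tumorSizeSdlog)
    annotations <- data.frame(
      sample_id = sn,
      er_status = factor(er, levels = c("POS", "NEG", "UNKNOWN")),
      subtype_label = unname(labels), tumor_size = size,
      stringsAsFactors = FALSE)
    planted <- stats::setNames(
      lapply(config$deSpec, function(d) gn[d$genes]),
      vapply(config$deSpec, function(d)
        paste(sort(d$pair), collapse = "|"), character(1L)))
    structure(list(expression = ExpressionMatrix(values),
                   trueLabels = labels,
                   annotations = annotations,
                   plantedCentroids = CentroidTable(centroids),
                   panel = gn[seq_len(max(config$nInformative, 0L))],
                   plantedDeGenes = planted,
                   ambiguousPairs = ambiguous,
                   config = config),
              class = "SimulatedCohort")
  })
}

#' @export
print.SimulatedCohort <- function(x, ...) {
  cat("SimulatedCohort: ", nrow(exprValues(x$expression)), " genes x ",
      length(x$trueLabels), " samples; classes ",
      paste(names(table(x$trueLabels)), table(x$trueLabels), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Balanced training split with per-class quotas
#'
#' Seeded without-replacement sampling of a fixed number of samples per
#' class (e.g. 50/50/50/50 for the four tumor classes plus 20 Normal-like,
#' a 220-sample training set); the test set is the complement. A quota
#' exceeding a class's availability is an error naming the class and
#' shortfall; quotas consuming every sample leave an empty test set, which
#' is flagged with a warning.
#'
#' @param labels sample-named character vector of class labels.
#' @param quotas named integer vector, class -> training count.
#' @param seed integer seed.
#' @return list with `train` and `test` character id vectors (disjoint;
#'   union = all samples).
#' @export
buildBalancedTrainingSplit <- function(labels, quotas, seed = 1L) {
  labels <- .callVector(labels)
  stopifnot(!is.null(names(quotas)))
  counts <- table(labels)
  for (k in names(quotas)) {
    avail <- if (k %in% names(counts)) as.integer(counts[k]) else 0L
    if (quotas[k] > avail)
      stop("quota for class ", k, " (", quotas[k], ") exceeds available ",
           avail, " samples (shortfall ", quotas[k] - avail, ")")
  }
  train <- .withSeed(seed, unlist(lapply(names(quotas), function(k)
    sample(names(labels)[labels == k], quotas[k])), use.names = FALSE))
  test <- setdiff(names(labels), train)
  if (!length(test)) warning("training quotas consume every sample: ",
                             "test set is empty")
  list(train = train, test = test)
}

#' Simulate data from a known sparse softmax model
#'
#' Draws standard-normal features and class labels from a softmax model
#' whose weight matrix is non-zero only on a small set of active genes --
#' the ground truth for support-recovery checks of the elastic-net
#' logistic regression.
#'
#' @param nSamples,nGenes,nClasses problem dimensions.
#' @param nActive number of genes with non-zero true weights.
#' @param effectSize magnitude of the non-zero weights.
#' @param seed integer seed.
#' @return list: `expression` ([ExpressionMatrix-class]), `labels`,
#'   `trueSupport` (active gene names), `weights` (true K x G matrix).
#' @export
simulateSparseSoftmax <- function(nSamples = 300L, nGenes = 60L,
                                  nClasses = 3L, nActive = 10L,
                                  effectSize = 2, seed = 1L) {
  stopifnot(nActive <= nGenes, nClasses >= 2L)
  gn <- .geneNames(nGenes)
  sn <- .sampleNames(nSamples)
  classes <- paste0("C", seq_len(nClasses))
  .withSeed(seed, {
    X <- matrix(stats::rnorm(nSamples * nGenes), nSamples, nGenes,
                dimnames = list(sn, gn))
    W <- matrix(0, nClasses, nGenes, dimnames = list(classes, gn))
    active <- seq_len(nActive)
    # each active gene discriminates a random pair of classes (+effect vs
    # -effect); a same-sign-in-every-class pattern would be a softmax shift
    # invariant, i.e. nominally "active" but carrying no signal
    for (g in active) {
      kk <- sample.int(nClasses, 2L)
      W[kk[1L], g] <- effectSize
      W[kk[2L], g] <- -effectSize
    }
    P <- .softmaxProbs(X %*% t(W))
    y <- vapply(seq_len(nSamples), function(i)
      sample(classes, 1L, prob = P[i, ]), character(1L))
    list(expression = ExpressionMatrix(t(X)),
         labels = stats::setNames(y, sn),
         trueSupport = gn[active], weights = W)
  })
}
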