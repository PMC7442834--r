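# Feature selection: four univariate filter rankings (Fisher, mutual
# information, chi-squared, Spearman one-vs-rest), pairwise-contrast DEG
# "limmaN" union signatures, and randomized multi-run backward elimination
# with union-of-kept genes.

.newRanking <- function(metric, scores) {
  stopifnot(!is.null(names(scores)), all(is.finite(scores)))
  ord <- names(scores)[order(-scores, names(scores), method = "radix")]
  structure(list(metric = metric, scores = scores, order = ord),
            class = "FeatureRanking")
}

#' @export
print.FeatureRanking <- function(x, ...) {
  cat("FeatureRanking (", x$metric, "): ", length(x$scores), " genes; top: ",
      paste(utils::head(x$order, 5L), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.newSignature <- function(name, geneIds, provenance) {
  geneIds <- unique(geneIds)
  if (!length(geneIds)) stop("a gene signature cannot be empty")
  structure(list(name = name, genes = geneIds, provenance = provenance),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat("GeneSignature '", x$name, "': ", length(x$genes), " genes (method: ",
      x$provenance$method %||% "?", ")\n", sep = "")
  invisible(x)
}

.labelVector <- function(expr, labels) {
  labels <- .callVector(labels)
  labels <- labels[sampleIDs(expr)]
  if (anyNA(labels)) stop("labels missing for some samples")
  labels
}

#' Fisher scores
#'
#' Per gene, `F = sum_k n_k (mu_k - mu)^2 / sum_k n_k sigma_k^2` with
#' population (biased) within-class variances and the overall mean `mu`;
#' the denominator is floored at 1e-12, so zero within-class variance with
#' distinct means yields a large finite score.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param labels SubtypeCallSet or sample-named character vector (every
#'   class needs >= 2 samples).
#' @return a `FeatureRanking`.
#' @export
fisherScores <- function(expr, labels) {
  labels <- .labelVector(expr, labels)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need >= 2 classes")
  if (any(sizes < 2L))
    stop("class with < 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  v <- exprValues(expr)
  mu <- rowMeans(v)
  num <- 0; den <- 0
  for (k in names(sizes)) {
    vk <- v[, labels == k, drop = FALSE]
    nk <- ncol(vk)
    muk <- rowMeans(vk)
    vark <- rowMeans((vk - muk)^2)  # population variance
    num <- num + nk * (muk - mu)^2
    den <- den + nk * vark
  }
  .newRanking("fisher", num / pmax(den, 1e-12))
}

# Per-gene quantile binning: bin ids 1..<=bins; constant genes collapse to a
# single occupied bin.
.quantileBins <- function(x, bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L)))
  if (length(br) < 2L) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Mutual-information scores
#'
#' Per gene: expression discretized into per-gene quantile bins, then the
#' plug-in mutual information (in bits) between the binned expression and
#' the class label. A constant gene occupies a single bin and scores 0.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param labels class labels.
#' @param bins number of quantile bins (default 4).
#' @return a `FeatureRanking`.
#' @export
mutualInformationScores <- function(expr, labels, bins = 4L) {
  stopifnot(bins >= 2L)
  labels <- .labelVector(expr, labels)
  v <- exprValues(expr)
  mi <- apply(v, 1L, function(x) {
    tab <- table(.quantileBins(x, bins), labels)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  })
  .newRanking("mutual_information", mi)
}

#' Chi-squared scores
#'
#' Per gene, the Pearson chi-squared statistic of the quantile-bin x class
#' contingency table (no continuity correction). Uniform independent counts
#' and constant genes score 0.
#'
#' @inheritParams mutualInformationScores
#' @return a `FeatureRanking`.
#' @export
chiSquaredScores <- function(expr, labels, bins = 4L) {
  stopifnot(bins >= 2L)
  labels <- .labelVector(expr, labels)
  v <- exprValues(expr)
  chi <- apply(v, 1L, function(x) {
    tab <- table(.quantileBins(x, bins), labels)
    if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
    unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic))
  })
  .newRanking("chi_squared", chi)
}

#' Spearman one-vs-rest label correlation scores
#'
#' The class label enters a correlation through its one-vs-rest indicator:
#' per gene, the maximum over classes of the absolute Spearman correlation
#' between expression and the 0/1 indicator of that class. Constant genes
#' score 0.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param labels class labels.
#' @return a `FeatureRanking`.
#' @export
spearmanLabelScores <- function(expr, labels) {
  labels <- .labelVector(expr, labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need >= 2 classes")
  v <- exprValues(expr)
  rk <- t(apply(v, 1L, rank, ties.method = "average"))
  sc <- rep(0, nrow(v))
  for (k in classes) {
    ind <- rank(as.numeric(labels == k), ties.method = "average")
    r <- suppressWarnings(abs(as.numeric(stats::cor(t(rk), ind))))
    r[is.na(r)] <- 0
    sc <- pmax(sc, r)
  }
  .newRanking("spearman_label", stats::setNames(sc, rownames(v)))
}

#' Top-k genes of a ranking
#'
#' @param ranking a `FeatureRanking`.
#' @param k number of genes, `1 <= k <= length(ranking$scores)`.
#' @return a `GeneSignature` of the first `k` genes in ranking order
#'   (descending score, ties alphabetical -- deterministic).
#' @export
topK <- function(ranking, k) {
  stopifnot(inherits(ranking, "FeatureRanking"))
  if (k < 1L || k > length(ranking$order))
    stop("k = ", k, " out of range [1, ", length(ranking$order), "]")
  .newSignature(paste0("top", k, "_", ranking$metric),
                ranking$order[seq_len(k)],
                list(method = "filter_top_k", metric = ranking$metric, k = k))
}

#' Pairwise-contrast differential expression
#'
#' One differential analysis per unordered class pair (C(K,2) contrasts,
#' e.g. 10 for 5 subtypes). Per gene a two-sample t-statistic on the log2
#' values; with `moderation = "empirical_bayes"` (default) the per-gene
#' variances are shrunk toward a pooled prior via limma's moderated t.
#' P-values are Benjamini-Hochberg adjusted within each contrast;
#' `significantGenes` are the genes with adjusted p < alpha, ordered by
#' ascending adjusted p (ties by gene name).
#'
#' @param expr an [ExpressionMatrix-class] (log2 scale).
#' @param labels class labels (each contrasted class needs >= 2 samples).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param moderation `"empirical_bayes"` (limma) or `"none"` (pooled
#'   ordinary t).
#' @return list of `ContrastResult` objects, one per pair, in canonical
#'   pair order.
#' @export
pairwiseDEG <- function(expr, labels, alpha = 0.05,
                        moderation = c("empirical_bayes", "none")) {
  moderation <- match.arg(moderation)
  labels <- .labelVector(expr, labels)
  classes <- .canonicalOrder(unique(labels))
  if (length(classes) < 2L) stop("need >= 2 classes")
  v <- exprValues(expr)
  pairs <- utils::combn(classes, 2L)
  lapply(seq_len(ncol(pairs)), function(pi) {
    a <- pairs[1L, pi]; b <- pairs[2L, pi]
    ia <- labels == a; ib <- labels == b
    if (sum(ia) < 2L || sum(ib) < 2L)
      stop("contrast ", a, " vs ", b, " has a class with < 2 samples")
    if (moderation == "empirical_bayes") {
      sub <- v[, ia | ib, drop = FALSE]
      grp <- factor(labels[ia | ib], levels = c(b, a))
      design <- stats::model.matrix(~grp)
      fit <- limma::eBayes(limma::lmFit(sub, design))
      stat <- fit$t[, 2L]
      pval <- fit$p.value[, 2L]
    } else {
      na <- sum(ia); nb <- sum(ib)
      ma <- rowMeans(v[, ia, drop = FALSE])
      mb <- rowMeans(v[, ib, drop = FALSE])
      va <- rowSums((v[, ia, drop = FALSE] - ma)^2)
      vb <- rowSums((v[, ib, drop = FALSE] - mb)^2)
      df <- na + nb - 2L
      sp2 <- (va + vb) / df
      stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
      pval <- 2 * stats::pt(-abs(stat), df)
    }
    adj <- stats::p.adjust(pval, method = "BH")
    gs <- rownames(v)
    sigOrd <- gs[adj < alpha][order(adj[adj < alpha], gs[adj < alpha],
                                    method = "radix")]
    structure(list(classPair = c(a, b),
                   table = data.frame(gene = gs, statistic = stat,
                                      p_value = pval, adj_p_value = adj,
                                      row.names = NULL),
                   significantGenes = sigOrd, alpha = alpha,
                   moderation = moderation),
              class = "ContrastResult")
  })
}

#' @export
print.ContrastResult <- function(x, ...) {
  cat("ContrastResult ", x$classPair[1L], " vs ", x$classPair[2L], ": ",
      length(x$significantGenes), " significant genes (BH < ", x$alpha,
      ", ", x$moderation, ")\n", sep = "")
  invisible(x)
}

#' limmaN union signature
#'
#' Union, over all pairwise contrasts, of the top `N` significant genes of
#' each contrast (or all of them when a list is shorter than `N`): every
#' gene in the signature is relevant to distinguishing at least one pair of
#' subtypes. Monotone in `N`.
#'
#' @param contrasts list of `ContrastResult`s from [pairwiseDEG].
#' @param N per-contrast truncation.
#' @return a `GeneSignature` named `limma<N>`; provenance records the
#'   per-contrast contributions.
#' @export
limmaNSignature <- function(contrasts, N) {
  stopifnot(N >= 1L, length(contrasts) >= 1L)
  tops <- lapply(contrasts, function(cr)
    utils::head(cr$significantGenes, N))
  if (!any(lengths(tops) > 0L))
    stop("every contrast's significant-gene list is empty")
  contrib <- stats::setNames(tops, vapply(contrasts, function(cr)
    paste(cr$classPair, collapse = "_vs_"), character(1L)))
  .newSignature(paste0("limma", N), unlist(tops, use.names = FALSE),
                list(method = "limmaN", N = N, contributions = contrib))
}

#' Randomized multi-run backward elimination
#'
#' Wrapper feature selection. Each run shuffles the gene order (seeded),
#' then sweeps the genes once per pass: a gene is removed when the
#' cross-validated accuracy without it exceeds the current accuracy by more
#' than `gainThreshold`; passes repeat until a full sweep removes nothing.
#' Because the sequential sweep is order-biased, several runs with
#' randomized feature order are performed and the final signature is the
#' union of every run's kept set.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param labels class labels.
#' @param start a `GeneSignature` (or character vector) to prune.
#' @param trainer function `(expr, labels, geneSubset, seed) ->` mean CV
#'   accuracy in `[0, 1]`; defaults to a seeded 5-fold cross-validated
#'   elastic-net multiclass logistic regression ([crossValidateMLR] with
#'   l1 = l2 = 0.01).
#' @param gainThreshold minimum accuracy gain to accept a removal (default
#'   0.001; `Inf` disables all removals).
#' @param runs independent randomized runs (default 10).
#' @param seed master seed.
#' @param folds inner CV folds for the default trainer (default 5).
#' @return a `GeneSignature`; provenance records each run's kept set and
#'   any aborted runs.
#' @export
backwardElimination <- function(expr, labels, start, trainer = NULL,
                                gainThreshold = 0.001, runs = 10L, seed = 1L,
                                folds = 5L) {
  startGenes <- if (inherits(start, "GeneSignature")) start$genes
                else as.character(start)
  if (!length(startGenes)) stop("start signature is empty")
  stopifnot(runs >= 1L)
  if (is.null(trainer))
    trainer <- function(expr, labels, geneSubset, seed) {
      cv <- crossValidateMLR(expr[geneSubset, ], labels, folds = folds,
                             l1 = 0.01, l2 = 0.01, seed = seed)
      cv$meanAccuracy
    }
  labels <- .labelVector(expr, labels)
  seeds <- .subSeeds(seed, runs)
  keptSets <- list(); failures <- list()
  for (r in seq_len(runs)) {
    res <- tryCatch({
      current <- .withSeed(seeds[r], sample(startGenes))
      acc <- trainer(expr, labels, current, seeds[r])
      repeat {
        removed <- FALSE
        for (g in current) {
          if (length(current) <= 1L) break
          cand <- setdiff(current, g)
          accWithout <- trainer(expr, labels, cand, seeds[r])
          if (accWithout > acc + gainThreshold) {
            current <- cand
            acc <- accWithout
            removed <- TRUE
          }
        }
        if (!removed) break
      }
      current
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("backward-elimination run ", r, " aborted: ",
              conditionMessage(res))
      failures[[length(failures) + 1L]] <-
        list(run = r, reason = conditionMessage(res))
    } else keptSets[[length(keptSets) + 1L]] <- res
  }
  if (!length(keptSets))
    stop("all backward-elimination runs failed")
  kept <- startGenes[startGenes %in% unlist(keptSets)]
  .newSignature("bwe_union", kept,
                list(method = "backward_elimination",
                     gain_threshold = gainThreshold, runs = runs,
                     seed = seed, kept_per_run = keptSets,
                     aborted_runs = failures))
}
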