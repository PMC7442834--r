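# Elastic-net-regularized multiclass (softmax) logistic regression.
# Objective, over per-gene z-scored features:
#   F(W, b) = (1/n) * multinomial NLL + l1 * sum|W| + (l2/2) * sum W^2
# with intercepts b unpenalized. Optimized by proximal gradient descent
# (ISTA with backtracking line search): gradient step on the smooth part
# (NLL + ridge), soft-thresholding for the lasso part, which produces exact
# zeros in the weight matrix.

.softmaxProbs <- function(Z) {
  Z <- Z - apply(Z, 1L, max)  # shift invariance, numerical stability
  E <- exp(Z)
  E / rowSums(E)
}

# Smooth part of the objective and its gradients. X: n x G standardized,
# Y: n x K one-hot, W: K x G, b: length K.
.mlrSmooth <- function(X, Y, W, b, l2) {
  n <- nrow(X)
  Z <- X %*% t(W) + matrix(b, n, length(b), byrow = TRUE)
  P <- .softmaxProbs(Z)
  nll <- -sum(Y * log(pmax(P, 1e-300))) / n
  val <- nll + (l2 / 2) * sum(W^2)
  D <- (P - Y) / n
  list(value = val, gradW = t(D) %*% X + l2 * W, gradB = colSums(D), P = P)
}

.softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Full penalized objective.
.mlrObjective <- function(X, Y, W, b, l1, l2) {
  .mlrSmooth(X, Y, W, b, l2)$value + l1 * sum(abs(W))
}

.oneHot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(names(labels), classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

.standardizeFit <- function(X) {
  ctr <- colMeans(X)
  sc <- pmax(apply(X, 2L, stats::sd), 1e-8)
  list(center = ctr, scale = sc, Z = sweep(sweep(X, 2L, ctr), 2L, sc, "/"))
}

#' Fit an elastic-net multiclass logistic regression
#'
#' @param expr an [ExpressionMatrix-class]; its genes are the feature space.
#' @param labels SubtypeCallSet or sample-named character vector (>= 2
#'   classes).
#' @param l1,l2 non-negative lasso / ridge penalty strengths.
#' @param maxIterations proximal-gradient iteration cap (default 1000; a
#'   warning is logged when reached without convergence).
#' @param tol relative-objective-change convergence tolerance (default
#'   1e-6).
#' @param seed recorded in the fit metadata (the optimizer itself is
#'   deterministic from its zero initialization).
#' @return a fitted [MLRModel-class]. Class order is canonical
#'   (alphabetical).
#' @export
fitMLR <- function(expr, labels, l1 = 0.01, l2 = 0.01,
                   maxIterations = 1000L, tol = 1e-6, seed = NA_integer_) {
  stopifnot(is(expr, "ExpressionMatrix"), l1 >= 0, l2 >= 0)
  labels <- .labelVector(expr, labels)
  classes <- .canonicalOrder(unique(labels))
  if (length(classes) < 2L) stop("single-class input: need >= 2 classes")
  X <- t(exprValues(expr))  # n x G
  std <- .standardizeFit(X)
  Z <- std$Z
  Y <- .oneHot(labels, classes)
  K <- length(classes); G <- ncol(Z)
  W <- matrix(0, K, G, dimnames = list(classes, colnames(Z)))
  b <- stats::setNames(rep(0, K), classes)
  step <- 1
  sm <- .mlrSmooth(Z, Y, W, b, l2)
  obj <- sm$value + l1 * sum(abs(W))
  if (!is.finite(obj)) stop("non-finite objective at initialization")
  converged <- FALSE
  iter <- 0L
  trace <- obj
  while (iter < maxIterations) {
    iter <- iter + 1L
    repeat {
      Wn <- .softThreshold(W - step * sm$gradW, step * l1)
      bn <- b - step * sm$gradB
      smn <- .mlrSmooth(Z, Y, Wn, bn, l2)
      dW <- Wn - W; db <- bn - b
      quad <- sm$value + sum(sm$gradW * dW) + sum(sm$gradB * db) +
        (sum(dW^2) + sum(db^2)) / (2 * step)
      if (smn$value <= quad + 1e-12 || step < 1e-12) break
      step <- step / 2
    }
    W <- Wn; b <- bn; sm <- smn
    newObj <- sm$value + l1 * sum(abs(W))
    if (!is.finite(newObj)) stop("non-finite objective during optimization")
    trace <- c(trace, newObj)
    if (abs(obj - newObj) <= tol * max(1, abs(obj))) {
      obj <- newObj
      converged <- TRUE
      break
    }
    obj <- newObj
    step <- step * 1.25  # cautious step growth after an accepted iterate
  }
  if (!converged)
    warning("fitMLR reached ", maxIterations,
            " iterations without meeting tolerance ", tol)
  new("MLRModel", classes = classes, featureGenes = genes(expr),
      weights = W, intercepts = b, center = std$center, scale = std$scale,
      l1 = l1, l2 = l2,
      fitMeta = list(seed = seed, iterations = iter, objective = obj,
                     converged = converged, trace = trace))
}

#' Predict subtype memberships with a fitted MLR model
#'
#' Applies the stored training standardization, computes softmax membership
#' probabilities per sample (they sum to one), and calls the arg-max class
#' with the canonical alphabetical tie-break. Genes absent from the model's
#' feature set are ignored; model feature genes missing from the matrix are
#' an error.
#'
#' @param model a fitted [MLRModel-class].
#' @param expr an [ExpressionMatrix-class] containing every feature gene.
#' @return a [SubtypeCallSet-class] with membership scores.
#' @export
predictMLR <- function(model, expr) {
  stopifnot(is(model, "MLRModel"), is(expr, "ExpressionMatrix"))
  miss <- setdiff(model@featureGenes, genes(expr))
  if (length(miss))
    stop("model feature gene(s) missing from expression matrix: ",
         paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) ", ..." else "")
  X <- t(exprValues(expr)[model@featureGenes, , drop = FALSE])
  Z <- sweep(sweep(X, 2L, model@center), 2L, model@scale, "/")
  logits <- Z %*% t(model@weights) +
    matrix(model@intercepts, nrow(Z), length(model@classes), byrow = TRUE)
  P <- .softmaxProbs(logits)
  dimnames(P) <- list(rownames(X), model@classes)
  call <- vapply(seq_len(nrow(P)), function(i)
    .argmaxCanonical(P[i, ]), character(1L))
  SubtypeCallSet(stats::setNames(call, rownames(P)), P,
                 scoreType = "membership")
}

# Seeded stratified fold assignment: per class, shuffled ids dealt
# round-robin, so per-class fold counts differ by at most one.
.stratifiedFolds <- function(labels, folds, seed) {
  assign <- stats::setNames(integer(length(labels)), names(labels))
  .withSeed(seed, {
    offset <- 0L
    for (k in sort(unique(labels))) {
      ids <- sample(names(labels)[labels == k])
      assign[ids] <- ((seq_along(ids) + offset - 1L) %% folds) + 1L
      offset <- offset + length(ids)
    }
  })
  assign
}

#' Stratified cross-validation of the MLR classifier
#'
#' Seeded stratified partition (per-class fold counts within one of exact
#' proportionality); per fold, the model -- including the feature
#' standardization -- is refit on the training split only and scored on the
#' held-out fold.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param labels class labels.
#' @param folds number of folds (default 10); reduced with a warning when a
#'   class has fewer samples than folds.
#' @param l1,l2 penalty strengths.
#' @param seed integer seed (drives the fold partition).
#' @param ... forwarded to [fitMLR].
#' @return list of class `CVResult`: `foldAssignments`, `foldAccuracy`,
#'   `meanAccuracy`, `sdAccuracy`, `folds`.
#' @export
crossValidateMLR <- function(expr, labels, folds = 10L, l1 = 0.01,
                             l2 = 0.01, seed = 1L, ...) {
  labels <- .labelVector(expr, labels)
  minClass <- min(table(labels))
  if (minClass < folds) {
    warning("smallest class has ", minClass, " samples; reducing folds from ",
            folds, " to ", minClass)
    folds <- minClass
  }
  if (folds < 2L) stop("cross-validation needs >= 2 folds")
  assign <- .stratifiedFolds(labels, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    testIds <- names(assign)[assign == f]
    trainIds <- names(assign)[assign != f]
    fit <- fitMLR(expr[, trainIds], labels[trainIds], l1 = l1, l2 = l2,
                  seed = seed, ...)
    pred <- predictMLR(fit, expr[, testIds])
    mean(calls(pred) == labels[testIds])
  }, numeric(1L))
  structure(list(foldAssignments = assign, foldAccuracy = acc,
                 meanAccuracy = mean(acc),
                 sdAccuracy = if (folds > 1L) stats::sd(acc) else 0,
                 folds = folds),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat("CVResult: ", x$folds, "-fold; accuracy ",
      sprintf("%.3f +/- %.3f", x$meanAccuracy, x$sdAccuracy), "\n", sep = "")
  invisible(x)
}

#' Elastic-net hyperparameter grid search
#'
#' Cross-validates every (l1, l2) cell with the same seeded folds, selects
#' the cell with maximal mean CV accuracy (exact ties broken by smaller l1,
#' then smaller l2), and refits the winner on all data.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param labels class labels.
#' @param l1Grid,l2Grid non-empty numeric grids (default
#'   `c(0.01, 0.1, 1)` each).
#' @param folds CV folds (default 10).
#' @param seed integer seed.
#' @param ... forwarded to [fitMLR].
#' @return list: `model` (refit winner), `report` (data.frame l1, l2,
#'   mean_accuracy, sd_accuracy), `best` (winning row index).
#' @export
gridSearchMLR <- function(expr, labels, l1Grid = c(0.01, 0.1, 1),
                          l2Grid = c(0.01, 0.1, 1), folds = 10L, seed = 1L,
                          ...) {
  stopifnot(length(l1Grid) >= 1L, length(l2Grid) >= 1L)
  grid <- expand.grid(l1 = sort(l1Grid), l2 = sort(l2Grid))
  res <- lapply(seq_len(nrow(grid)), function(i)
    crossValidateMLR(expr, labels, folds = folds, l1 = grid$l1[i],
                     l2 = grid$l2[i], seed = seed, ...))
  report <- data.frame(grid,
                       mean_accuracy = vapply(res, `[[`, numeric(1L),
                                              "meanAccuracy"),
                       sd_accuracy = vapply(res, `[[`, numeric(1L),
                                            "sdAccuracy"))
  best <- order(-report$mean_accuracy, report$l1, report$l2)[1L]
  model <- fitMLR(expr, labels, l1 = report$l1[best], l2 = report$l2[best],
                  seed = seed, ...)
  list(model = model, report = report, best = best)
}

#' Count non-zero weights of a fitted model
#'
#' @param model an [MLRModel-class].
#' @param threshold magnitude above which a weight counts as non-zero
#'   (default 1e-8, the optimizer's zero threshold).
#' @return integer count.
#' @export
nonZeroWeights <- function(model, threshold = 1e-8) {
  sum(abs(modelWeights(model)) > threshold)
}
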