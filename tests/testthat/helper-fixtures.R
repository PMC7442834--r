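# Fixtures are built in code; nothing is stored on disk.

# Tiny 5-gene expression matrix with two samples.
toyExpression <- function() {
  ExpressionMatrix(matrix(c(2, 1, 4, 3, 5,
                            5, 4, 3, 2, 1),
                          nrow = 5,
                          dimnames = list(paste0("G", 1:5), c("s1", "s2"))))
}

# Two perfectly anti-correlated 5-gene centroids.
toyCentroids <- function() {
  CentroidTable(matrix(c(1, 2, 3, 4, 5,
                         5, 4, 3, 2, 1),
                       nrow = 5,
                       dimnames = list(paste0("G", 1:5), c("A", "B"))))
}

zeroReference <- function(geneIds) {
  ReferenceProfile(stats::setNames(rep(0, length(geneIds)), geneIds))
}

# Small noisy cohort for pipeline-level tests (3 classes keeps fits fast).
smallCohortConfig <- function(seed = 1L, noiseSd = 1, ambiguousFraction = 0.1,
                              nGenes = 200L, nInformative = 40L) {
  simulationConfig(nGenes = nGenes, nInformative = nInformative,
                   classSizes = c(LumA = 40L, LumB = 30L, Basal = 30L),
                   erPosProb = c(LumA = 0.9, LumB = 0.85, Basal = 0.1),
                   noiseSd = noiseSd, ambiguousFraction = ambiguousFraction,
                   seed = seed)
}

panelCentroids <- function(cohort) {
  CentroidTable(exprValues(cohort$plantedCentroids)[cohort$panel, ,
                                                    drop = FALSE])
}

# Pearson correlation from first principles (sums formula), used as the
# independent arm of rank-correlation oracles.
handPearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Construct a ContrastResult directly (bookkeeping tests for limmaN).
fakeContrast <- function(a, b, sig) {
  structure(list(classPair = c(a, b),
                 table = data.frame(gene = sig,
                                    statistic = rep(NA_real_, length(sig)),
                                    p_value = rep(NA_real_, length(sig)),
                                    adj_p_value = rep(NA_real_, length(sig))),
                 significantGenes = sig, alpha = 0.05, moderation = "none"),
            class = "ContrastResult")
}

# Two-class cohort with one informative and one pure-noise gene, for
# backward-elimination tests. Returns expression + labels.
informativePlusNoise <- function(n_per_class = 20L, shift = 2, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  inf <- c(rnorm(n_per_class, 0), rnorm(n_per_class, shift))
  noise <- rnorm(n, sd = 2)
  ids <- sprintf("S%03d", seq_len(n))
  m <- rbind(INF = inf, NOISE = noise)
  colnames(m) <- ids
  list(expr = ExpressionMatrix(m),
       labels = stats::setNames(rep(c("A", "B"), each = n_per_class), ids))
}

# Deterministic CV-accuracy trainer for backward elimination: accuracy is a
# fixed function of the gene subset (exercises the algorithm's mechanics
# independently of any model fit).
stubTrainer <- function(table) {
  function(expr, labels, geneSubset, seed) {
    key <- paste(sort(geneSubset), collapse = "+")
    if (!key %in% names(table)) stop("stub trainer: unknown subset ", key)
    table[[key]]
  }
}
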