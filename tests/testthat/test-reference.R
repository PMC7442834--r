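makeAnnotations <- function(nPos, nNeg, nUnk = 0L) {
  n <- nPos + nNeg + nUnk
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             er_status = factor(rep(c("POS", "NEG", "UNKNOWN"),
                                    c(nPos, nNeg, nUnk)),
                                levels = c("POS", "NEG", "UNKNOWN")),
             stringsAsFactors = FALSE)
}

test_that("ER-stratified subsets honour quotas and seeds", {
  ann <- makeAnnotations(300, 200, 10)
  s10 <- sampleERStratifiedSubset(ann, 10, 0.6, seed = 1)
  er <- ann$er_status[match(s10, ann$sample_id)]
  expect_equal(sum(er == "POS"), 6)
  expect_equal(sum(er == "NEG"), 4)

  s400 <- sampleERStratifiedSubset(ann, 400, 0.6, seed = 1)
  er <- ann$er_status[match(s400, ann$sample_id)]
  expect_equal(sum(er == "POS"), 240)
  expect_equal(sum(er == "NEG"), 160)
  expect_false(any(er == "UNKNOWN"))

  expect_identical(sampleERStratifiedSubset(ann, 50, 0.6, seed = 7),
                   sampleERStratifiedSubset(ann, 50, 0.6, seed = 7))
  expect_false(identical(sampleERStratifiedSubset(ann, 50, 0.6, seed = 7),
                         sampleERStratifiedSubset(ann, 50, 0.6, seed = 8)))
})

test_that("insufficient strata raise errors naming the shortfall", {
  ann <- makeAnnotations(500, 3)
  expect_error(sampleERStratifiedSubset(ann, 400, 0.6, seed = 1),
               "ER-.*need 160.*have 3.*shortfall 157")
})

test_that("median reference matches the sort-and-pick oracle", {
  m <- matrix(c(1, 1, 2, 2, 10, 3, 4, 10), nrow = 2,
              dimnames = list(c("ODD", "EVEN"), paste0("s", 1:4)))
  # gene ODD over first 3 samples: {1, 2, 10} -> 2
  ref3 <- buildMedianReference(ExpressionMatrix(m), paste0("s", 1:3))
  expect_equal(unname(refValues(ref3)["ODD"]), 2)
  # gene EVEN over all 4: {1, 2, 3, 10} -> 2.5
  ref4 <- buildMedianReference(ExpressionMatrix(m), paste0("s", 1:4))
  expect_equal(unname(refValues(ref4)["EVEN"]), 2.5)

  # identical samples -> that profile; single sample -> that sample
  one <- ExpressionMatrix(matrix(c(3, 7, 3, 7), 2,
                                 dimnames = list(c("A", "B"),
                                                 c("s1", "s2"))))
  expect_equal(unname(refValues(buildMedianReference(one, c("s1", "s2")))),
               c(3, 7))
  expect_equal(unname(refValues(buildMedianReference(one, "s1"))), c(3, 7))
  expect_error(buildMedianReference(one, "nope"), "unknown sample id")
})

test_that("AWCA is the unweighted mean of within-class means", {
  m <- matrix(c(1, 3, 3, 5, 2, 6, 6, 2), nrow = 2,
              dimnames = list(c("G1", "G2"), paste0("s", 1:4)))
  em <- ExpressionMatrix(m)
  labels <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  ref <- buildAwcaReference(em, labels, minClassSize = 1L)
  # G1: class means 2 and 4 -> 3
  expect_equal(unname(refValues(ref)["G1"]), 3)
  expect_equal(unname(refValues(ref)["G2"]), 4)

  # three classes, one excluded -> mean over the other two only
  m3 <- cbind(m, s5 = c(100, 100))
  labels3 <- c(labels, s5 = "NormalLike")
  ref3 <- buildAwcaReference(ExpressionMatrix(m3), labels3,
                             excludedClasses = "NormalLike",
                             minClassSize = 1L)
  expect_equal(refValues(ref3), refValues(ref))
})

test_that("AWCA is exactly invariant to within-class duplication; median is not", {
  co <- simulateCohort(smallCohortConfig(seed = 3L, nGenes = 50L,
                                         nInformative = 20L))
  em <- co$expression
  labels <- co$trueLabels
  ref <- buildAwcaReference(em, labels, minClassSize = 1L)

  # duplicate every LumA sample 3x (recompute-from-scratch oracle)
  dupIds <- names(labels)[labels == "LumA"]
  aug <- cbind(exprValues(em),
               exprValues(em)[, rep(dupIds, 2), drop = FALSE])
  colnames(aug) <- make.unique(colnames(aug))
  augLabels <- stats::setNames(labels[sub("\\.\\d+$", "", colnames(aug))],
                               colnames(aug))
  refAug <- buildAwcaReference(ExpressionMatrix(aug), augLabels,
                               minClassSize = 1L)
  expect_identical(refValues(refAug), refValues(ref))

  # witness: the median reference shifts under the same skewed duplication
  med <- buildMedianReference(em, sampleIDs(em))
  medAug <- buildMedianReference(ExpressionMatrix(aug), colnames(aug))
  expect_gt(max(abs(refValues(medAug) - refValues(med))), 0)
})

test_that("AWCA drops undersized classes and requires two survivors", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("s", 1:10)))
  labels <- stats::setNames(c(rep("A", 5), rep("B", 4), "C"),
                            paste0("s", 1:10))
  expect_message(
    ref <- buildAwcaReference(ExpressionMatrix(m), labels, minClassSize = 2L),
    "auto-excluded.*C=1")
  byHand <- (rowMeans(m[, 1:5]) + rowMeans(m[, 6:9])) / 2
  expect_equal(refValues(ref), byHand)
  expect_error(buildAwcaReference(ExpressionMatrix(m), labels,
                                  minClassSize = 6L),
               "class sizes: A=5, B=4, C=1")
})

test_that("references are invariant to sample order", {
  co <- simulateCohort(smallCohortConfig(seed = 4L, nGenes = 40L,
                                         nInformative = 15L))
  em <- co$expression
  set.seed(1)
  perm <- sample(sampleIDs(em))
  emP <- em[, perm]
  expect_equal(refValues(buildMedianReference(em, sampleIDs(em)[1:30])),
               refValues(buildMedianReference(emP, sampleIDs(em)[1:30])))
  expect_equal(refValues(buildAwcaReference(em, co$trueLabels,
                                            minClassSize = 1L)),
               refValues(buildAwcaReference(emP, co$trueLabels[perm],
                                            minClassSize = 1L)))
})

test_that("the AWCA pipeline recovers a noiseless cohort exactly", {
  co <- simulateCohort(smallCohortConfig(noiseSd = 0, ambiguousFraction = 0))
  pipe <- suppressWarnings(suppressMessages(
    awcaPipeline(co$expression, co$annotations, panelCentroids(co),
                 subsetSize = 40, seed = 1, minClassSize = 5L)))
  expect_equal(as.numeric(concordance(pipe$finalCalls, co$trueLabels)), 100)
})

test_that("the pipeline is deterministic and warns on tiny subsets", {
  co <- simulateCohort(smallCohortConfig(seed = 6L))
  run <- function(seed) suppressWarnings(suppressMessages(
    awcaPipeline(co$expression, co$annotations, panelCentroids(co),
                 subsetSize = 40, seed = seed, minClassSize = 5L)))
  a <- run(11); b <- run(11)
  expect_identical(calls(a$finalCalls), calls(b$finalCalls))
  expect_identical(refValues(a$reference), refValues(b$reference))
  expect_warning(
    suppressMessages(awcaPipeline(co$expression, co$annotations,
                                  panelCentroids(co), subsetSize = 40,
                                  seed = 1, minClassSize = 5L)),
    "below the recommended minimum")
})

test_that("the pipeline accepts precomputed labels in place of the subset step", {
  co <- simulateCohort(smallCohortConfig(seed = 9L))
  pipe <- suppressMessages(
    awcaPipeline(co$expression, centroids = panelCentroids(co),
                 preliminaryCalls = co$trueLabels, minClassSize = 5L))
  expect_null(pipe$medianReference)
  byHand <- buildAwcaReference(co$expression, co$trueLabels,
                               minClassSize = 5L)
  expect_identical(refValues(pipe$reference), refValues(byHand))
})

test_that("AWCA re-classification is at least as stable as the preliminary calls", {
  co <- simulateCohort(smallCohortConfig(seed = 12L))
  run <- function(seed) suppressWarnings(suppressMessages(
    awcaPipeline(co$expression, co$annotations, panelCentroids(co),
                 subsetSize = 40, seed = seed, minClassSize = 5L)))
  a <- run(101); b <- run(202)
  prelim <- as.numeric(concordance(a$preliminaryCalls, b$preliminaryCalls))
  final <- as.numeric(concordance(a$finalCalls, b$finalCalls))
  expect_gte(final, prelim)
})

test_that("the stability experiment reports perfect scores on noiseless data", {
  co <- simulateCohort(smallCohortConfig(noiseSd = 0, ambiguousFraction = 0))
  rep <- suppressWarnings(suppressMessages(stabilityExperiment(
    co$expression, co$annotations, panelCentroids(co), sizes = c(40, 20),
    replicates = 3, truthLabels = co$trueLabels, seed = 5,
    minClassSize = 5L)))
  expect_true(all(rep$summary$mean_truth == 100))
  expect_true(all(rep$summary$mean_pairwise == 100))
  expect_true(all(rep$summary$sd_pairwise == 0))
  expect_equal(nrow(rep$pairwise[rep$pairwise$size == 40 &
                                 rep$pairwise$strategy == "awca", ]),
               choose(3, 2))
})

test_that("a single replicate yields empty, flagged pairwise lists", {
  co <- simulateCohort(smallCohortConfig(seed = 13L, nGenes = 60L,
                                         nInformative = 25L))
  rep <- suppressWarnings(suppressMessages(stabilityExperiment(
    co$expression, co$annotations, panelCentroids(co), sizes = 40,
    replicates = 1, truthLabels = co$trueLabels, seed = 5,
    minClassSize = 5L)))
  expect_equal(nrow(rep$pairwise), 0)
  expect_true(all(is.na(rep$summary$mean_pairwise)))
})

test_that("infeasible subset sizes are skipped with a warning and reported", {
  co <- simulateCohort(smallCohortConfig(seed = 14L, nGenes = 60L,
                                         nInformative = 25L))
  w <- testthat::capture_warnings(
    rep <- suppressMessages(stabilityExperiment(
      co$expression, co$annotations, panelCentroids(co),
      sizes = c(40, 5000), replicates = 2, truthLabels = co$trueLabels,
      seed = 5, minClassSize = 5L)))
  expect_match(w, "skipped", all = TRUE)
  expect_length(w, 2L)
  expect_equal(nrow(rep$skipped), 2)
  expect_false(5000 %in% rep$summary$size)
})
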