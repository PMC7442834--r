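# Risk-of-recurrence (ROR) scoring downstream of classification: a weighted
# sum of per-class centroid correlations plus a tumor-size term (the ROR-C
# form), optional affine rescaling, and low/intermediate/high binning.
# Coefficients and thresholds are user configuration, never package
# constants: the published Cox coefficients must be transcribed by the user
# (see inst/extdata/ror_placeholder_synthetic.tsv for the config layout).

#' Compute a ROR score for one classified sample
#'
#' `raw = sum_k w_k * rho_k + w_T * T`, then `a * raw + b` when a rescaling
#' is configured. Risk groups: score <= lower threshold -> "low";
#' <= upper threshold -> "intermediate"; else "high" (boundary values fall
#' in the lower group).
#'
#' @param scores named numeric vector of per-class correlations for one
#'   sample (e.g. one row of `callScores()`).
#' @param tumorSize tumor-size covariate; required (non-NA) when the model's
#'   tumor-size weight is non-zero.
#' @param model a [RORModel-class].
#' @return list with `raw_score` (after rescaling) and `risk_group`.
#' @export
computeROR <- function(scores, tumorSize = NA_real_, model) {
  stopifnot(is(model, "RORModel"))
  w <- model@classWeights
  rho <- scores[names(w)]
  bad <- names(w)[is.na(rho) & w != 0]
  if (length(bad))
    stop("missing correlation for weighted class(es): ",
         paste(bad, collapse = ", "))
  rho[is.na(rho)] <- 0
  raw <- sum(w * rho)
  if (model@tumorSizeWeight != 0) {
    if (is.na(tumorSize))
      stop("tumor size is required (tumor-size weight is non-zero)")
    raw <- raw + model@tumorSizeWeight * tumorSize
  }
  raw <- model@rescale[1L] * raw + model@rescale[2L]
  group <- if (raw <= model@thresholds[1L]) "low"
           else if (raw <= model@thresholds[2L]) "intermediate"
           else "high"
  list(raw_score = raw, risk_group = group)
}

#' Batch ROR scoring
#'
#' Vectorized [computeROR] over a call set; output order matches input
#' order. Per-sample failures (missing correlations or tumor size) are
#' collected and reported in the result, never silently dropped.
#'
#' @param callSet a [SubtypeCallSet-class].
#' @param annotations data.frame with sample_id and tumor_size (may be
#'   omitted when the model's tumor-size weight is zero).
#' @param model a [RORModel-class].
#' @return data.frame with columns sample_id, raw_score, risk_group, ok,
#'   reason (NA for scored samples).
#' @export
rorBatch <- function(callSet, annotations = NULL, model) {
  stopifnot(is(callSet, "SubtypeCallSet"))
  ids <- sampleIDs(callSet)
  sizes <- rep(NA_real_, length(ids))
  if (!is.null(annotations))
    sizes <- annotations$tumor_size[match(ids, annotations$sample_id)]
  sc <- callScores(callSet)
  rows <- lapply(seq_along(ids), function(i) {
    res <- tryCatch(computeROR(sc[i, ], sizes[i], model),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(sample_id = ids[i], raw_score = NA_real_,
                 risk_group = NA_character_, ok = FALSE,
                 reason = conditionMessage(res))
    else
      data.frame(sample_id = ids[i], raw_score = res$raw_score,
                 risk_group = res$risk_group, ok = TRUE,
                 reason = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load a ROR model from a key-value TSV config
#'
#' Two-column TSV (key, value). Keys: `weight:<class>` for class weights,
#' `tumor_size_weight`, `threshold_low`, `threshold_high`, and optional
#' `rescale_a` / `rescale_b`.
#'
#' @param path config file path.
#' @return a [RORModel-class].
#' @export
loadRORModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", colClasses = "character",
                          stringsAsFactors = FALSE)
  kv <- stats::setNames(as.numeric(df[[2L]]), df[[1L]])
  wk <- grep("^weight:", names(kv), value = TRUE)
  if (!length(wk)) stop("ROR config ", path, " defines no class weights")
  RORModel(classWeights = stats::setNames(kv[wk], sub("^weight:", "", wk)),
           tumorSizeWeight = unname(kv["tumor_size_weight"] %na% 0),
           thresholds = c(unname(kv["threshold_low"] %na% 0),
                          unname(kv["threshold_high"] %na% 1)),
           rescale = c(unname(kv["rescale_a"] %na% 1),
                       unname(kv["rescale_b"] %na% 0)))
}

`%na%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a
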