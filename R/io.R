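# On-disk formats. Canonical dialect for every table: UTF-8, tab-separated,
# one header row, first column = identifier, no quoting. Lines starting with
# '#' are provenance comments and are skipped on read. Loading never mutates
# numeric values.

MODEL_SCHEMA_VERSION <- "awca-mlr-1"

.readTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

# Convert the non-identifier columns of a character data.frame to a numeric
# matrix, reporting the coordinates of the first non-numeric cell.
.numericBody <- function(df, path) {
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate identifier in ", path, ": ", ids[duplicated(ids)][1L])
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(ids, colnames(body))))
  bad <- which(is.na(num) & !(body %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric value '", body[bad[1L, 1L], bad[1L, 2L]], "' in ", path,
         " at row '", ids[bad[1L, 1L]], "', column '",
         colnames(body)[bad[1L, 2L]], "'")
  if (anyNA(num))
    stop("missing value in ", path, " at row '",
         ids[which(is.na(num), arr.ind = TRUE)[1L, 1L]],
         "' (missing expression values are rejected, not imputed)")
  num
}

#' Load an expression matrix from TSV
#'
#' Reads a tab-separated log2-scale expression table (one header row, first
#' column = identifier). Values are taken verbatim; duplicated identifiers,
#' missing and non-numeric cells are errors. Gene symbols are upper-cased.
#'
#' @param path TSV file path.
#' @param orientation `"genes_by_samples"` (default; rows are genes) or
#'   `"samples_by_genes"` (rows are samples; the matrix is transposed to the
#'   canonical genes x samples layout).
#' @return an [ExpressionMatrix-class].
#' @export
loadExpression <- function(path,
                           orientation = c("genes_by_samples",
                                           "samples_by_genes")) {
  orientation <- match.arg(orientation)
  num <- .numericBody(.readTSV(path), path)
  if (orientation == "samples_by_genes") num <- t(num)
  ExpressionMatrix(num)
}

#' Write an expression matrix to TSV
#'
#' @param expr an [ExpressionMatrix-class].
#' @param path output path.
#' @param idColumn name of the identifier column header (default "gene").
#' @param header optional character vector of provenance comment lines
#'   (written prefixed with "# ").
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path, idColumn = "gene",
                            header = character()) {
  .writeMatrixTSV(exprValues(expr), path, idColumn, header)
}

.writeMatrixTSV <- function(m, path, idColumn, header = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c(idColumn, colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = "\t"), character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Load a centroid table from TSV
#'
#' Genes in rows, one column per class; class column order is preserved as in
#' the file. Fewer than two classes or any missing value is an error.
#'
#' @param path TSV file path.
#' @return a [CentroidTable-class].
#' @export
loadCentroids <- function(path) {
  num <- .numericBody(.readTSV(path), path)
  if (ncol(num) < 2L)
    stop("centroid table ", path, " has ", ncol(num),
         " class column(s); at least 2 classes are required")
  CentroidTable(num)
}

#' Write a centroid table to TSV
#'
#' @param centroids a [CentroidTable-class].
#' @param path output path.
#' @param header optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
writeCentroids <- function(centroids, path, header = character()) {
  .writeMatrixTSV(exprValues(centroids), path, "gene", header)
}

#' Load a reference profile from two-column TSV (gene, value)
#'
#' @param path TSV file path.
#' @param method construction record to attach (default "external").
#' @return a [ReferenceProfile-class].
#' @export
loadReference <- function(path, method = "external") {
  df <- .readTSV(path)
  if (ncol(df) != 2L)
    stop("reference file ", path, " must have exactly two columns (gene, value)")
  num <- .numericBody(df, path)
  ReferenceProfile(stats::setNames(num[, 1L], rownames(num)), method = method)
}

#' Write a reference profile to two-column TSV
#'
#' @param ref a [ReferenceProfile-class].
#' @param path output path.
#' @param header optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
writeReference <- function(ref, path, header = character()) {
  m <- matrix(refValues(ref), ncol = 1L,
              dimnames = list(genes(ref), "value"))
  .writeMatrixTSV(m, path, "gene", header)
}

#' Load per-sample cohort annotations
#'
#' Expects a TSV with a header naming at least `sample_id`; optional columns
#' `er_status` (POS/NEG, anything else or absent becomes UNKNOWN),
#' `subtype_label` (validated against `classVocabulary` when given) and
#' `tumor_size` (non-negative numeric).
#'
#' @param path TSV file path.
#' @param classVocabulary optional character vector of admissible subtype
#'   labels.
#' @return data.frame with columns sample_id, er_status (factor
#'   POS/NEG/UNKNOWN), subtype_label (character or NA), tumor_size (numeric
#'   or NA).
#' @export
loadAnnotations <- function(path, classVocabulary = NULL) {
  df <- .readTSV(path)
  if (!"sample_id" %in% colnames(df))
    stop("annotation file ", path, " lacks a 'sample_id' column")
  ids <- df[["sample_id"]]
  if (anyDuplicated(ids))
    stop("duplicate sample_id in ", path, ": ", ids[duplicated(ids)][1L])
  er <- if ("er_status" %in% colnames(df)) {
    e <- toupper(df[["er_status"]])
    e[!(e %in% c("POS", "NEG"))] <- "UNKNOWN"
    e
  } else rep("UNKNOWN", length(ids))
  lab <- if ("subtype_label" %in% colnames(df)) {
    l <- df[["subtype_label"]]
    l[l == ""] <- NA_character_
    l
  } else rep(NA_character_, length(ids))
  if (!is.null(classVocabulary)) {
    bad <- setdiff(stats::na.omit(unique(lab)), classVocabulary)
    if (length(bad))
      stop("subtype_label '", bad[1L], "' in ", path,
           " is outside the class vocabulary (",
           paste(classVocabulary, collapse = ", "), ")")
  }
  size <- if ("tumor_size" %in% colnames(df)) {
    s <- suppressWarnings(as.numeric(df[["tumor_size"]]))
    if (any(!is.na(s) & s < 0)) stop("negative tumor_size in ", path)
    s
  } else rep(NA_real_, length(ids))
  data.frame(sample_id = ids,
             er_status = factor(er, levels = c("POS", "NEG", "UNKNOWN")),
             subtype_label = lab, tumor_size = size,
             stringsAsFactors = FALSE)
}

#' Write cohort annotations to TSV
#'
#' @param annotations data.frame as returned by [loadAnnotations].
#' @param path output path.
#' @param header optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(annotations, path, header = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(annotations, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a call set to TSV
#'
#' One row per sample: sample_id, call, and one score column per class.
#'
#' @param callSet a [SubtypeCallSet-class].
#' @param path output path.
#' @param header optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
writeCalls <- function(callSet, path, header = character()) {
  sc <- callScores(callSet)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("sample_id", "call", colnames(sc)), collapse = "\t"), con)
  cl <- calls(callSet)
  body <- vapply(seq_along(cl), function(i)
    paste(c(names(cl)[i], cl[i], .fmtNum(sc[i, ])), collapse = "\t"),
    character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Load a call set from TSV
#'
#' @param path TSV written by [writeCalls].
#' @param scoreType score semantics ("correlation" or "membership").
#' @return a [SubtypeCallSet-class].
#' @export
loadCalls <- function(path, scoreType = "correlation") {
  df <- .readTSV(path)
  if (!all(c("sample_id", "call") %in% colnames(df)))
    stop("call file ", path, " must have sample_id and call columns")
  ids <- df[["sample_id"]]
  classes <- setdiff(colnames(df), c("sample_id", "call"))
  sc <- matrix(suppressWarnings(as.numeric(as.matrix(df[, classes,
                                                        drop = FALSE]))),
               nrow = nrow(df), dimnames = list(ids, classes))
  SubtypeCallSet(stats::setNames(df[["call"]], ids), sc, scoreType = scoreType)
}

# ---- model serialization ----------------------------------------------------

#' Save a fitted MLR model to a versioned text schema
#'
#' Plain-text, tab-separated, field-per-line schema. Numbers are written with
#' 17 significant digits, so `loadModel(saveModel(m))` reproduces every field
#' bit-identically.
#'
#' @param model an [MLRModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  validObject(model)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ln <- function(...) writeLines(paste(..., sep = "\t"), con)
  ln("schema", MODEL_SCHEMA_VERSION)
  ln("classes", paste(model@classes, collapse = ","))
  ln("features", paste(model@featureGenes, collapse = ","))
  ln("l1", .fmtNum(model@l1))
  ln("l2", .fmtNum(model@l2))
  ln("seed", as.character(model@fitMeta$seed %||% NA))
  ln("iterations", as.character(model@fitMeta$iterations %||% NA))
  ln("objective", .fmtNum(model@fitMeta$objective %||% NA_real_))
  ln("converged", as.character(isTRUE(model@fitMeta$converged)))
  ln("intercepts", paste(.fmtNum(model@intercepts), collapse = "\t"))
  ln("center", paste(.fmtNum(model@center), collapse = "\t"))
  ln("scale", paste(.fmtNum(model@scale), collapse = "\t"))
  for (k in seq_along(model@classes))
    ln(paste0("weights:", model@classes[k]),
       paste(.fmtNum(model@weights[k, ]), collapse = "\t"))
  ln("end", "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a fitted MLR model from its text schema
#'
#' @param path file written by [saveModel].
#' @return an [MLRModel-class].
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(fields, `[`, character(1L), 1L)
  get1 <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("model file ", path, " is truncated or corrupt: ",
                       "missing field '", key, "'")
    fields[[i]][-1L]
  }
  schema <- get1("schema")
  if (!identical(schema, MODEL_SCHEMA_VERSION))
    stop("model schema version mismatch in ", path, ": found '", schema,
         "', expected '", MODEL_SCHEMA_VERSION, "'")
  if (!"end" %in% keys)
    stop("model file ", path, " is truncated (no end marker)")
  classes <- strsplit(get1("classes"), ",", fixed = TRUE)[[1L]]
  features <- strsplit(get1("features"), ",", fixed = TRUE)[[1L]]
  W <- t(vapply(classes, function(k)
    as.numeric(get1(paste0("weights:", k))), numeric(length(features))))
  dimnames(W) <- list(classes, features)
  meta <- list(seed = suppressWarnings(as.integer(get1("seed"))),
               iterations = suppressWarnings(as.integer(get1("iterations"))),
               objective = suppressWarnings(as.numeric(get1("objective"))),
               converged = identical(get1("converged"), "TRUE"))
  new("MLRModel", classes = classes, featureGenes = features, weights = W,
      intercepts = stats::setNames(as.numeric(get1("intercepts")), classes),
      center = stats::setNames(as.numeric(get1("center")), features),
      scale = stats::setNames(as.numeric(get1("scale")), features),
      l1 = as.numeric(get1("l1")), l2 = as.numeric(get1("l2")),
      fitMeta = meta)
}
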