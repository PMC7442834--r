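# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All randomness in the package flows
# through this, so seeds never leak between operations.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seeds derived from a master seed (kept below 2^31).
.subSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Canonical class order: fixed alphabetical (C locale) ordering of class
# names, used for every deterministic tie-break.
.canonicalOrder <- function(classes) {
  classes[order(classes, method = "radix")]
}

# Arg-max with canonical alphabetical tie-break over a named numeric vector
# (NA entries ignored).
.argmaxCanonical <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  top <- names(x)[x == max(x)]
  .canonicalOrder(top)[1L]
}

# Average-rank transform of each column of a matrix.
.rankColumns <- function(m) {
  apply(m, 2L, rank, ties.method = "average")
}

# Normalize a calls argument: SubtypeCallSet or named character -> named
# character vector.
.callVector <- function(x) {
  if (is(x, "SubtypeCallSet")) return(calls(x))
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("expected a SubtypeCallSet or a sample-named character vector of calls")
}

# Full-precision decimal rendering that round-trips doubles exactly.
.fmtNum <- function(x) sprintf("%.17g", x)
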