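# Internal helpers shared across modules.

## Canonical string key for a face (subset of variable indices).
.faceKey <- function(idx) paste(sort(as.integer(idx)), collapse = ";")

.keyToFace <- function(key) as.integer(strsplit(key, ";", fixed = TRUE)[[1L]])

## Shannon entropy in bits of a probability vector; 0 * log 0 := 0.
.entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

## Evaluate `code` under a temporary RNG state seeded with `seed`.
## seed = NULL leaves the caller's RNG stream untouched (and consumed).
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## All non-empty subsets of an index vector, as a list, ordered by
## (cardinality, lexicographic order of members).
## combn() misreads a length-1 vector as a count; guard explicitly.
.combnList <- function(idx, k) {
  if (length(idx) == 1L)
    return(if (k == 1L) list(idx) else list())
  cmb <- utils::combn(idx, k)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

.allSubsets <- function(idx, kmax = length(idx)) {
  idx <- sort(as.integer(idx))
  out <- vector("list", 0L)
  for (k in seq_len(min(kmax, length(idx))))
    out <- c(out, .combnList(idx, k))
  out
}

## Collapse the rows of an integer code matrix into atom keys.
.rowKeys <- function(codes) {
  if (ncol(codes) == 1L) as.character(codes[, 1L])
  else do.call(paste, c(lapply(seq_len(ncol(codes)), function(j) codes[, j]),
                        sep = ","))
}

.assertSubsetOf <- function(subset, vars, what = "subset") {
  subset <- as.integer(subset)
  if (length(subset) == 0L)
    stop(what, " must be non-empty", call. = FALSE)
  if (anyDuplicated(subset))
    stop(what, " must not contain duplicated indices", call. = FALSE)
  if (!all(subset %in% vars))
    stop(what, " contains indices outside the available variables",
         call. = FALSE)
  subset
}
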