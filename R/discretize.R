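## Binning and empirical probability estimation.
##
## Probabilities are estimated by elementary counting over an equal-width
## grid: each variable's interval [min, max] is split into N_j bins and the
## atomic probability of a box is the fraction of samples falling in it.

#' Compute an equal-width binning scheme
#'
#' The graining interval of each variable is bounded by its minimum and
#' maximum measured values; the interval is divided into \code{N} equal
#' width bins. A constant variable collapses to a single bin (silent genes
#' are common in expression matrices and are kept with entropy zero rather
#' than rejected).
#'
#' @param x a \code{\link{DataMatrix}}.
#' @param N integer bin count, either a scalar applied to every variable or
#'   one value per variable. Default 9.
#' @return a \code{\link{BinningScheme}}.
#' @examples
#' x <- DataMatrix(cbind(a = 0:8, b = seq(-1, 1, length.out = 9)))
#' computeBins(x, N = 3)
#' @export
computeBins <- function(x, N = 9L) {
  stopifnot(is(x, "DataMatrix"))
  n <- nVariables(x)
  N <- as.integer(N)
  if (length(N) == 1L) N <- rep(N, n)
  if (length(N) != n) stop("N must be scalar or one value per variable")
  if (any(N < 1L)) stop("bin counts must be >= 1")
  lo <- apply(x@values, 2L, min)
  hi <- apply(x@values, 2L, max)
  new("BinningScheme", nBins = N, lo = as.numeric(lo), hi = as.numeric(hi),
      varLabels = variableLabels(x))
}

#' Discretize a data matrix under a binning scheme
#'
#' Each value is mapped to the code
#' \code{min(floor((x - lo) * N / (hi - lo)), N - 1)}, so bins are
#' half-open with the maximum value assigned to the last bin, and a value
#' lying exactly on an interior boundary goes to the higher bin. Constant
#' variables (\code{lo == hi}) receive code 0.
#'
#' @param x a \code{\link{DataMatrix}}.
#' @param scheme a \code{\link{BinningScheme}}; default
#'   \code{computeBins(x, N)}.
#' @param N bin count used when \code{scheme} is not supplied.
#' @return a \code{\link{DiscreteMatrix}}.
#' @examples
#' x <- DataMatrix(cbind(v = c(0, 1, 2, 3, 10), w = c(5, 5, 5, 5, 5)))
#' codes(discretize(x, N = 2))
#' @export
discretize <- function(x, scheme = NULL, N = 9L) {
  stopifnot(is(x, "DataMatrix"))
  if (is.null(scheme)) scheme <- computeBins(x, N)
  stopifnot(is(scheme, "BinningScheme"))
  if (length(scheme@nBins) != nVariables(x))
    stop("scheme does not match the number of variables")
  m <- nSamples(x)
  out <- matrix(0L, m, nVariables(x), dimnames = dimnames(x@values))
  for (j in seq_len(ncol(out))) {
    v <- x@values[, j]
    lo <- scheme@lo[j]; hi <- scheme@hi[j]; Nj <- scheme@nBins[j]
    if (any(v < lo) || any(v > hi))
      stop("values of variable ", j, " fall outside the scheme interval")
    if (hi == lo) next           # constant variable: single bin, code 0
    out[, j] <- pmin(as.integer(floor((v - lo) * Nj / (hi - lo))), Nj - 1L)
  }
  new("DiscreteMatrix", codes = out, scheme = scheme)
}

#' Estimate the empirical joint distribution on a subset of variables
#'
#' The probability of a code tuple is the number of samples carrying those
#' codes on the subset divided by \eqn{m}. By locality, estimating on a
#' subset coincides with marginalizing the full-joint estimate.
#'
#' @param x a \code{\link{DiscreteMatrix}}.
#' @param subset non-empty integer vector of distinct variable indices.
#' @return a \code{\link{JointDist}} whose support has at most
#'   \code{min(m, prod(N_j))} atoms.
#' @examples
#' dm <- discretize(DataMatrix(cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))),
#'                  N = 2)
#' estimateJoint(dm, 1:2)
#' @export
estimateJoint <- function(x, subset = seq_len(nVariables(x))) {
  stopifnot(is(x, "DiscreteMatrix"))
  subset <- .assertSubsetOf(subset, seq_len(nVariables(x)))
  sub <- x@codes[, subset, drop = FALSE]
  keys <- .rowKeys(sub)
  counts <- table(keys)
  atoms <- do.call(rbind, lapply(strsplit(names(counts), ",", fixed = TRUE),
                                 as.integer))
  new("JointDist", vars = subset, sizes = x@scheme@nBins[subset],
      atoms = atoms, probs = as.numeric(counts) / nrow(sub))
}

#' @describeIn infoGenerics Marginalize a joint distribution onto a
#'   sub-list of its variables by direct summation; total mass is
#'   preserved.
#' @param subset variable indices (a sub-list of \code{x@vars}).
#' @export
setMethod("marginalize", "JointDist", function(x, subset, ...) {
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  pos <- match(subset, x@vars)
  if (anyNA(pos)) stop("subset is not contained in the distribution's variables")
  atoms <- x@atoms[, pos, drop = FALSE]
  keys <- .rowKeys(atoms)
  agg <- rowsum(x@probs, keys)
  newAtoms <- do.call(rbind, lapply(strsplit(rownames(agg), ",", fixed = TRUE),
                                    as.integer))
  new("JointDist", vars = subset, sizes = x@sizes[pos],
      atoms = newAtoms, probs = as.numeric(agg))
})

#' Condition a joint distribution on an outcome of some of its variables
#'
#' Returns the conditional law of the remaining variables given that the
#' conditioning variables take the stated codes. Zero-probability outcomes
#' are an error (they are dropped upstream, following the 0 * Inf = 0
#' convention for conditional averages).
#'
#' @param x a \code{\link{JointDist}}.
#' @param condVars integer indices (subset of \code{x@vars}).
#' @param outcome integer codes, one per conditioning variable.
#' @return a \code{JointDist} on \code{setdiff(x@vars, condVars)}.
#' @export
conditionOn <- function(x, condVars, outcome) {
  stopifnot(is(x, "JointDist"))
  condVars <- as.integer(condVars)
  pos <- match(condVars, x@vars)
  if (anyNA(pos)) stop("conditioning variables not present")
  rest <- setdiff(seq_along(x@vars), pos)
  if (length(rest) == 0L) stop("cannot condition on every variable")
  hit <- rep(TRUE, nrow(x@atoms))
  for (i in seq_along(pos)) hit <- hit & x@atoms[, pos[i]] == outcome[i]
  mass <- sum(x@probs[hit])
  if (mass <= 0) stop("conditioning outcome has zero probability")
  new("JointDist", vars = x@vars[rest], sizes = x@sizes[rest],
      atoms = x@atoms[hit, rest, drop = FALSE], probs = x@probs[hit] / mass)
}
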