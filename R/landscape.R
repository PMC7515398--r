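## Landscapes: one information measure evaluated on every face of the
## simplicial lattice of variable subsets, up to a dimension cap.

#' Enumerate the faces of the simplicial lattice
#'
#' All \eqn{\sum_{k=1}^{k_{max}} \binom{n}{k}} non-empty variable subsets
#' of degree at most \code{kmax}, in (degree, lexicographic) order.
#'
#' @param n number of variables.
#' @param kmax dimension cap, \eqn{1 \le kmax \le n}.
#' @return list of integer vectors.
#' @examples
#' length(enumerateFaces(3, 3))   # 7
#' length(enumerateFaces(21, 2))  # 21 + 210
#' @export
enumerateFaces <- function(n, kmax = n) {
  n <- as.integer(n); kmax <- as.integer(kmax)
  if (kmax < 1L || kmax > n) stop("kmax must lie in [1, n]")
  .allSubsets(seq_len(n), kmax)
}

## Empirical joint entropy of a face of a code matrix, by counting
## distinct rows.
.faceEntropy <- function(codes, face) {
  keys <- .rowKeys(codes[, face, drop = FALSE])
  .entropyBits(as.numeric(table(keys)) / nrow(codes))
}

## Build an environment mapping face key -> empirical H for all faces up
## to kmax. Reused by landscapes, path search and the undersampling scan.
.hTable <- function(codes, kmax) {
  env <- new.env(parent = emptyenv(), size = 2048L)
  faces <- .allSubsets(seq_len(ncol(codes)), kmax)
  for (f in faces) assign(.faceKey(f), .faceEntropy(codes, f), envir = env)
  env
}

## Ik of a face from a (complete) H table, by the alternating sum.
.ikFromH <- function(henv, face) {
  total <- 0
  for (tset in .allSubsets(face)) {
    total <- total + (-1)^(length(tset) - 1) * get(.faceKey(tset), envir = henv)
  }
  total
}

#' Compute an information landscape
#'
#' Evaluates joint entropy (\code{"H"}), mutual information (\code{"I"})
#' or total correlation (\code{"G"}) on every face up to degree
#' \code{kmax}, from the empirical joints of a discretized matrix. The
#' number of faces grows as \eqn{O(2^n)}; a guard refuses runs whose face
#' count exceeds \code{maxFaces}.
#'
#' @param x a \code{\link{DiscreteMatrix}}.
#' @param measure one of \code{"H"}, \code{"I"}, \code{"G"}.
#' @param kmax dimension cap (default \code{min(n, 3)}).
#' @param maxFaces guard on the total face count (default \code{2e5}).
#' @param ku optional known undersampling dimension, recorded in the
#'   metadata; a warning is emitted when \code{kmax} exceeds it.
#' @return an \code{\link{InfoLandscape}}.
#' @examples
#' dm <- discretize(independentSamples(3, 2, 64, seed = 1), N = 2)
#' computeLandscape(dm, "I", kmax = 3)
#' @export
computeLandscape <- function(x, measure = c("H", "I", "G"), kmax = NULL,
                             maxFaces = 2e5, ku = NULL) {
  stopifnot(is(x, "DiscreteMatrix"))
  measure <- match.arg(measure)
  n <- nVariables(x)
  if (is.null(kmax)) kmax <- min(n, 3L)
  kmax <- as.integer(kmax)
  if (kmax < 1L || kmax > n) stop("kmax must lie in [1, n]")
  nFaces <- sum(choose(n, seq_len(kmax)))
  if (nFaces > maxFaces)
    stop("lattice has ", nFaces, " faces, exceeding maxFaces = ", maxFaces)
  if (!is.null(ku) && kmax > ku)
    warning("kmax = ", kmax, " exceeds the undersampling dimension ku = ", ku)
  faces <- enumerateFaces(n, kmax)
  henv <- .hTable(x@codes, kmax)
  keys <- vapply(faces, .faceKey, character(1))
  degrees <- lengths(faces)
  values <- switch(measure,
    H = vapply(keys, function(k) get(k, envir = henv), numeric(1),
               USE.NAMES = FALSE),
    I = vapply(faces, function(f) .ikFromH(henv, f), numeric(1)),
    G = {
      h1 <- vapply(seq_len(n), function(v) get(.faceKey(v), envir = henv),
                   numeric(1))
      vapply(faces, function(f) sum(h1[f]) - get(.faceKey(f), envir = henv),
             numeric(1))
    })
  new("InfoLandscape", measure = measure, n = as.integer(n), kmax = kmax,
      keys = keys, degrees = as.integer(degrees), values = values,
      metadata = list(m = nSamples(x), N = binCounts(x), ku = ku,
                      varLabels = variableLabels(x)))
}

#' Mean information path of a landscape
#'
#' The arithmetic mean of the measure over all \eqn{\binom{n}{k}} faces of
#' each degree \eqn{k}, the quantity plotted in iso-graining and
#' iso-sample-size sweeps.
#'
#' @param landscape a complete \code{\link{InfoLandscape}}.
#' @return numeric vector of length \code{kmax}, named by degree.
#' @export
meanPath <- function(landscape) {
  stopifnot(is(landscape, "InfoLandscape"))
  counts <- tabulate(landscape@degrees, nbins = landscape@kmax)
  expected <- choose(landscape@n, seq_len(landscape@kmax))
  if (!all(counts == expected))
    stop("landscape is incomplete: found ", paste(counts, collapse = ","),
         " faces per degree, expected ", paste(expected, collapse = ","))
  out <- vapply(seq_len(landscape@kmax), function(k)
    mean(landscape@values[landscape@degrees == k]), numeric(1))
  names(out) <- seq_len(landscape@kmax)
  out
}

#' Extremal face of a landscape at one degree
#'
#' The face attaining the maximum (or minimum) measure value among all
#' faces of degree \code{k}; ties are broken by lexicographic order of the
#' face indices.
#'
#' @param landscape an \code{\link{InfoLandscape}}.
#' @param k face degree.
#' @param direction \code{"max"} or \code{"min"}.
#' @return integer vector of variable indices.
#' @export
maxTuple <- function(landscape, k, direction = c("max", "min")) {
  stopifnot(is(landscape, "InfoLandscape"))
  direction <- match.arg(direction)
  sel <- which(landscape@degrees == k)
  if (length(sel) == 0L) stop("no degree-", k, " entries in the landscape")
  vals <- landscape@values[sel]
  best <- if (direction == "max") max(vals) else min(vals)
  ## keys are stored in (degree, lexicographic) enumeration order, so the
  ## first hit is the lexicographically smallest tied face
  .keyToFace(landscape@keys[sel[which(vals == best)[1L]]])
}

#' First minimum of a mean information path
#'
#' The critical dimension of a mean path: the smallest degree whose value
#' is strictly below the next degree's value. \code{NA} when the path is
#' monotonically non-increasing (no non-trivial minimum, the disordered
#' regime).
#'
#' @param means numeric vector as returned by \code{\link{meanPath}}.
#' @return integer degree or \code{NA}.
#' @export
criticalDimension <- function(means) {
  if (length(means) < 2L) return(NA_integer_)
  for (k in seq_len(length(means) - 1L)) {
    if (means[k] < means[k + 1L]) return(k)
  }
  NA_integer_
}

#' Iso-graining / iso-sample-size landscape sweep
#'
#' For every combination of graining \code{N} and subsample size \code{m},
#' rebins the data, draws \code{m} rows without replacement, computes the
#' mean path of the requested measure, and reports its critical dimension.
#' Subsampling uses the seeded RNG; \code{m} equal to the full sample size
#' reproduces the direct mean path.
#'
#' @param x a \code{\link{DataMatrix}}.
#' @param NList integer vector of grainings to scan.
#' @param mList integer vector of subsample sizes (each at most the number
#'   of rows).
#' @param measure one of \code{"I"}, \code{"H"}, \code{"G"}.
#' @param kmax dimension cap for each landscape.
#' @param seed optional RNG seed for the subsampling.
#' @return data.frame with columns \code{N}, \code{m}, \code{degree},
#'   \code{mean}; the per-cell critical dimensions are attached as
#'   attribute \code{"criticalDim"} (data.frame \code{N}, \code{m},
#'   \code{kCritical}).
#' @export
landscapeSweep <- function(x, NList, mList, measure = "I", kmax = 3L,
                           seed = NULL) {
  stopifnot(is(x, "DataMatrix"))
  if (any(mList > nSamples(x)))
    stop("subsample sizes exceed the number of available samples")
  if (any(mList < 2L)) stop("subsample sizes must be >= 2")
  .withSeed(seed, {
    rows <- list(); crit <- list()
    for (N in NList) for (m in mList) {
      idx <- if (m == nSamples(x)) seq_len(nSamples(x))
             else sort(sample.int(nSamples(x), m))
      sub <- DataMatrix(x@values[idx, , drop = FALSE],
                        transposed = x@transposed)
      means <- meanPath(computeLandscape(discretize(sub, N = N),
                                         measure, kmax))
      rows[[length(rows) + 1L]] <-
        data.frame(N = N, m = m, degree = seq_along(means),
                   mean = as.numeric(means))
      crit[[length(crit) + 1L]] <-
        data.frame(N = N, m = m, kCritical = criticalDimension(means))
    }
    out <- do.call(rbind, rows)
    attr(out, "criticalDim") <- do.call(rbind, crit)
    out
  })
}
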