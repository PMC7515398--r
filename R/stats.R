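## Statistical guards: undersampling dimension, shuffle test of
## k-dependence, independence and Markov-consistency checks, and
## Monte-Carlo entropy bounds on the probability simplex.

#' Estimate the undersampling dimension
#'
#' Empirical joint entropies cannot exceed \eqn{\log_2 m}; a face whose
#' entropy sits at that ceiling is saturated (every sample occupies its
#' own box) and its value is a pure artefact of sample size. The
#' undersampling dimension \code{ku} is one less than the first degree at
#' which the fraction of saturated faces exceeds \code{pU}; measures above
#' \code{ku} should not be interpreted. Saturation propagates: every
#' extension of a saturated face is saturated.
#'
#' @param x a \code{\link{DiscreteMatrix}} with at least 2 samples and all
#'   bin counts at least 2.
#' @param pU saturation-probability threshold (default 0.05).
#' @param kmax highest degree scanned (default \code{min(n, 8)}).
#' @param tol absolute tolerance on the saturation equality
#'   \eqn{|H_k - \log_2 m| \le tol}.
#' @return an \code{\link{UndersamplingReport}}; \code{ku = kmax} when no
#'   degree saturates within the scan.
#' @examples
#' dm <- discretize(independentSamples(4, 3, 12, seed = 1), N = 3)
#' undersamplingDimension(dm, kmax = 4)
#' @export
undersamplingDimension <- function(x, pU = 0.05, kmax = NULL, tol = 1e-9) {
  stopifnot(is(x, "DiscreteMatrix"))
  if (any(binCounts(x) < 2L))
    stop("all variables need at least 2 bins for a non-trivial analysis")
  n <- nVariables(x); m <- nSamples(x)
  if (is.null(kmax)) kmax <- min(n, 8L)
  kmax <- as.integer(kmax)
  if (kmax < 1L || kmax > n) stop("kmax must lie in [1, n]")
  logm <- log2(m)
  henv <- .hTable(x@codes, kmax)
  sat <- numeric(kmax)
  for (k in seq_len(kmax)) {
    cmb <- utils::combn(n, k)
    hk <- vapply(seq_len(ncol(cmb)), function(j)
      get(.faceKey(cmb[, j]), envir = henv), numeric(1))
    sat[k] <- mean(abs(hk - logm) <= tol)
  }
  first <- which(sat > pU)
  ku <- if (length(first) == 0L) kmax else max(min(first) - 1L, 0L)
  new("UndersamplingReport", ku = as.integer(ku), saturation = sat,
      pU = pU, m = as.integer(m), n = as.integer(n), kmax = kmax)
}

#' Shuffle a discrete matrix column by column
#'
#' Independently permutes the samples of each variable, leaving every
#' marginal distribution exactly invariant (the per-variable multisets of
#' codes are unchanged) while destroying any specific joint structure.
#' This is the null-generating move of the k-dependence test.
#'
#' @param x a \code{\link{DiscreteMatrix}}.
#' @param seed optional RNG seed.
#' @return a \code{DiscreteMatrix} of the same shape and scheme.
#' @export
shuffleColumns <- function(x, seed = NULL) {
  stopifnot(is(x, "DiscreteMatrix"))
  .withSeed(seed, {
    codes <- x@codes
    for (j in seq_len(ncol(codes)))
      codes[, j] <- codes[sample.int(nrow(codes)), j]
    new("DiscreteMatrix", codes = codes, scheme = x@scheme)
  })
}

#' Shuffle test of k-dependence
#'
#' Tests every face of the requested degrees against a null of randomly
#' generated dependences that preserve the marginals: the data are
#' shuffled column-wise \code{nShuffles} times, the \eqn{I_k} of all
#' degree-\eqn{k} faces of all shuffles are pooled into one null
#' distribution per degree (\code{nShuffles} times \eqn{\binom{n}{k}}
#' values), and a face is flagged when its observed \eqn{I_k} falls beyond
#' the null's empirical quantiles. Degree 2 uses a one-sided upper test at
#' level \code{p2} (\eqn{I_2 \ge 0}); degrees 3 and above use a symmetric
#' two-sided test at total level \code{pk}, since \eqn{I_k} may be
#' negative.
#'
#' A flag means the dependence is specific relative to random
#' marginal-preserving dependence at this sample size, not a strict
#' rejection of independence.
#'
#' @param x a \code{\link{DiscreteMatrix}}.
#' @param kRange integer degrees to test (default \code{2:3}).
#' @param nShuffles number of column shuffles pooled (default 17).
#' @param p2 one-sided level for degree 2 (default 0.05).
#' @param pk total two-sided level for degrees >= 3 (default 0.1).
#' @param seed optional RNG seed.
#' @return a \code{\link{DependenceReport}}.
#' @export
dependenceTest <- function(x, kRange = 2:3, nShuffles = 17L, p2 = 0.05,
                           pk = 0.1, seed = NULL) {
  stopifnot(is(x, "DiscreteMatrix"))
  kRange <- sort(as.integer(kRange))
  n <- nVariables(x)
  if (min(kRange) < 2L || max(kRange) > n)
    stop("kRange must lie within [2, n]")
  if (nShuffles < 1L) stop("at least one shuffle is required")
  kmax <- max(kRange)
  .withSeed(seed, {
    obs <- computeLandscape(x, "I", kmax = kmax)
    nullVals <- vector("list", length(kRange))
    names(nullVals) <- as.character(kRange)
    for (s in seq_len(nShuffles)) {
      shuf <- computeLandscape(shuffleColumns(x), "I", kmax = kmax)
      for (k in kRange) {
        key <- as.character(k)
        nullVals[[key]] <- c(nullVals[[key]], shuf@values[shuf@degrees == k])
      }
    }
    nulls <- list()
    rows <- list()
    for (k in kRange) {
      key <- as.character(k)
      pool <- nullVals[[key]]
      minP <- if (k == 2L) p2 else pk / 2
      if (length(pool) * minP < 1)
        warning("degree ", k, ": ", length(pool), " pooled null values give ",
                "poor resolution at level ", minP)
      if (k == 2L) {
        lower <- -Inf
        upper <- stats::quantile(pool, 1 - p2, type = 1, names = FALSE)
        sided <- "one"; level <- p2
      } else {
        lower <- stats::quantile(pool, pk / 2, type = 1, names = FALSE)
        upper <- stats::quantile(pool, 1 - pk / 2, type = 1, names = FALSE)
        sided <- "two"; level <- pk
      }
      nulls[[key]] <- new("NullDistribution", degree = as.integer(k),
                          values = pool, nShuffles = as.integer(nShuffles),
                          lower = lower, upper = upper, level = level,
                          sided = sided)
      sel <- which(obs@degrees == k)
      o <- obs@values[sel]
      side <- ifelse(o > upper, "above", ifelse(o < lower, "below", "none"))
      rows[[key]] <- data.frame(face = obs@keys[sel], degree = k,
                                observed = o, lower = lower, upper = upper,
                                significant = side != "none", side = side,
                                stringsAsFactors = FALSE)
    }
    new("DependenceReport", table = do.call(rbind, c(rows, make.row.names = FALSE)),
        nulls = nulls,
        params = list(nShuffles = nShuffles, p2 = p2, pk = pk, seed = seed))
  })
}

#' @describeIn infoGenerics Independence criterion: \eqn{n} variables are
#'   statistically independent exactly when all \eqn{2^n - n - 1} mutual
#'   information quantities \eqn{I_k}, \eqn{k \ge 2}, vanish. Returns a
#'   list with \code{independent} (logical), \code{nChecked}, and
#'   \code{violations} (data.frame of offending faces ranked by
#'   \eqn{|I_k|}).
#' @param tol absolute tolerance on \eqn{|I_k|} (default 1e-10).
#' @export
setMethod("independenceCheck", "JointDist", function(x, tol = 1e-10, ...) {
  vars <- sort(x@vars)
  n <- length(vars)
  if (n < 2L) stop("independence needs at least two variables")
  faces <- Filter(function(f) length(f) >= 2L, .allSubsets(vars))
  vals <- vapply(faces, function(f) mutualInfo(x, f), numeric(1))
  bad <- which(abs(vals) > tol)
  ord <- bad[order(-abs(vals[bad]))]
  list(independent = length(bad) == 0L,
       nChecked = length(faces),
       violations = data.frame(
         face = vapply(faces[ord], .faceKey, character(1)),
         degree = lengths(faces[ord]),
         value = vals[ord], stringsAsFactors = FALSE))
})

#' @describeIn infoGenerics Independence criterion on the empirical joint
#'   of a discrete matrix.
#' @export
setMethod("independenceCheck", "DiscreteMatrix", function(x, tol = 1e-10, ...) {
  independenceCheck(estimateJoint(x), tol = tol)
})

#' Markov-consistency check of an ordering
#'
#' For a Markov chain in the order \eqn{X_{i_1} \to \dots \to X_{i_n}},
#' every mutual information joining the two endpoints through any subset
#' of intermediate variables collapses to the endpoint pair information:
#' \eqn{I_k(X_{i_1}; X_{j_1}; \dots; X_{j_{k-2}}; X_{i_n}) =
#' I_2(X_{i_1}; X_{i_n})}. This checks all \eqn{2^{n-2}} equalities for
#' the given ordering.
#'
#' @param x a \code{\link{JointDist}}.
#' @param ordering a permutation of \code{x@vars}.
#' @param tol absolute tolerance (default 1e-9).
#' @return list with \code{consistent} (logical) and \code{residuals}
#'   (data.frame: intermediate subset, Ik, I2, residual).
#' @export
markovConsistency <- function(x, ordering, tol = 1e-9) {
  stopifnot(is(x, "JointDist"))
  ordering <- as.integer(ordering)
  if (!setequal(ordering, x@vars) || length(ordering) != length(x@vars))
    stop("ordering must be a permutation of the distribution's variables")
  n <- length(ordering)
  if (n < 3L) stop("a chain needs at least three variables")
  a <- ordering[1L]; b <- ordering[n]
  interior <- ordering[-c(1L, n)]
  i2 <- mutualInfo(x, c(a, b))
  subsets <- c(list(integer(0)), .allSubsets(interior))
  res <- vapply(subsets, function(J) mutualInfo(x, c(a, J, b)) - i2,
                numeric(1))
  data <- data.frame(
    interior = vapply(subsets, function(J)
      if (length(J)) .faceKey(J) else "", character(1)),
    ik = res + i2, i2 = i2, residual = res, stringsAsFactors = FALSE)
  list(consistent = all(abs(res) <= tol), residuals = data)
}

## Vectorized entropy (bits) of the rows of a probability matrix.
.rowEntropyBits <- function(P) {
  Plog <- P
  pos <- P > 0
  Plog[pos] <- P[pos] * log2(P[pos])
  Plog[!pos] <- 0
  -rowSums(Plog)
}

## Flat-Dirichlet draws on the simplex over `states` states, as a
## (count x states) matrix (uniform distribution in affine coordinates).
.flatDirichlet <- function(count, states) {
  g <- matrix(stats::rexp(count * states), count, states)
  g / rowSums(g)
}

#' Monte-Carlo check of the simplex entropy lower bound
#'
#' Under the uniform (flat-Dirichlet) distribution on the simplex of laws
#' over \eqn{r^k} states, the probability that the joint entropy
#' \eqn{H_k} exceeds \eqn{\epsilon k \log_2 r} is at least
#' \eqn{1 - \epsilon} for \eqn{0 < \epsilon \le 1/e}. This draws laws,
#' computes their entropies, and reports the fraction at or below the
#' threshold, which must not exceed \eqn{\epsilon} (up to Monte-Carlo
#' error).
#'
#' @param r alphabet size per variable (default 2).
#' @param k number of variables (default 3).
#' @param epsilon bound parameter in \eqn{(0, 1/e]} (default \code{1/e}).
#' @param nDraws number of simplex draws (default 1e4).
#' @param seed optional RNG seed.
#' @return list with \code{fraction}, \code{threshold} (bits),
#'   \code{epsilon}, \code{nDraws}.
#' @export
simplexEntropyTest <- function(r = 2L, k = 3L, epsilon = exp(-1),
                               nDraws = 1e4, seed = NULL) {
  if (epsilon <= 0 || epsilon > exp(-1))
    stop("epsilon must lie in (0, 1/e]")
  states <- as.integer(r)^as.integer(k)
  threshold <- epsilon * k * log2(r)
  .withSeed(seed, {
    H <- .rowEntropyBits(.flatDirichlet(nDraws, states))
    list(fraction = mean(H <= threshold), threshold = threshold,
         epsilon = epsilon, nDraws = nDraws)
  })
}

## Index masks for the three binary marginals and three pairwise marginals
## of an 8-state triple law ordered as (x1, x2, x3) with x3 fastest:
## state s = 4 x1 + 2 x2 + x3 + 1.
.tripleMasks <- local({
  states <- expand.grid(x3 = 0:1, x2 = 0:1, x1 = 0:1)[, 3:1]
  list(states = states)
})

#' Vectorized I3 of binary-triple laws
#'
#' Computes the triple mutual information \eqn{I_3} (bits) of each row of
#' a matrix of 8-state probability vectors (states ordered
#' \eqn{(x_1, x_2, x_3)} with \eqn{x_3} varying fastest), by the
#' inclusion-exclusion sum of marginal and joint entropies. Used for
#' large Monte-Carlo sweeps of the \eqn{-1 \le I_3 \le 1} bounds.
#'
#' @param P numeric matrix with 8 columns; rows are probability vectors.
#' @return numeric vector of \eqn{I_3} values.
#' @export
tripleI3 <- function(P) {
  P <- as.matrix(P)
  if (ncol(P) != 8L) stop("P must have 8 columns")
  st <- .tripleMasks$states
  margH <- function(groupIdx) {
    G <- sapply(groupIdx, function(ix) rowSums(P[, ix, drop = FALSE]))
    if (is.null(dim(G))) G <- matrix(G, nrow = 1L)
    .rowEntropyBits(G)
  }
  split1 <- function(v) lapply(0:1, function(b) which(st[[v]] == b))
  split2 <- function(v, w) {
    out <- list()
    for (b in 0:1) for (c in 0:1)
      out[[length(out) + 1L]] <- which(st[[v]] == b & st[[w]] == c)
    out
  }
  h1 <- margH(split1("x1")); h2 <- margH(split1("x2")); h3 <- margH(split1("x3"))
  h12 <- margH(split2("x1", "x2"))
  h13 <- margH(split2("x1", "x3"))
  h23 <- margH(split2("x2", "x3"))
  h123 <- .rowEntropyBits(P)
  h1 + h2 + h3 - h12 - h13 - h23 + h123
}

#' Monte-Carlo sweep of the I3 bounds
#'
#' Draws binary-triple laws uniformly from the 8-state simplex and returns
#' their \eqn{I_3} values; the absolute bound \eqn{|I_3| \le 1} bit holds
#' for every draw and is attained only by the extremal configurations
#' (identical/opposite unbiased triples at \eqn{+1}, the two parity
#' distributions at \eqn{-1}).
#'
#' @param nDraws number of draws.
#' @param seed optional RNG seed.
#' @return numeric vector of \eqn{I_3} values, one per draw.
#' @export
tripleI3Sweep <- function(nDraws = 1e5, seed = NULL) {
  .withSeed(seed, tripleI3(.flatDirichlet(nDraws, 8L)))
}
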