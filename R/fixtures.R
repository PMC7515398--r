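## Synthetic distributions and sampled matrices with known information
## structure, used throughout the test suite and usable as simulation
## tools in their own right.

#' Extremal binary-triple distributions
#'
#' The six two- and four-atom binary-triple laws attaining the bounds
#' \eqn{|I_3| \le 1}: \code{"identical"} places mass 1/2 on (0,0,0) and
#' (1,1,1); \code{"opposite1"}, \code{"opposite2"}, \code{"opposite3"}
#' are the three variants in which one variable is the complement of the
#' other two (supports \{(1,0,0),(0,1,1)\}, \{(0,1,0),(1,0,1)\},
#' \{(0,0,1),(1,1,0)\}); all four give \eqn{I_3 = +1}.
#' \code{"parity-even"} is uniform on the even-parity tuples
#' \{000, 011, 101, 110\} (the third variable is the XOR of the first
#' two) and \code{"parity-odd"} uniform on the odd-parity tuples; both
#' are pairwise independent with unbiased marginals yet jointly dependent
#' (\eqn{I_3 = -1}, \eqn{H_3 = 2} bits) -- the Borromean configurations.
#'
#' @param kind which extremal law to build.
#' @return a \code{\link{JointDist}} on three binary variables.
#' @examples
#' mutualInfo(extremalTriple("identical"), 1:3)    #  1
#' mutualInfo(extremalTriple("parity-even"), 1:3)  # -1
#' @export
extremalTriple <- function(kind = c("identical", "opposite1", "opposite2",
                                    "opposite3", "parity-even", "parity-odd")) {
  kind <- match.arg(kind)
  atoms <- switch(kind,
    "identical"   = rbind(c(0L, 0L, 0L), c(1L, 1L, 1L)),
    "opposite1"   = rbind(c(1L, 0L, 0L), c(0L, 1L, 1L)),
    "opposite2"   = rbind(c(0L, 1L, 0L), c(1L, 0L, 1L)),
    "opposite3"   = rbind(c(0L, 0L, 1L), c(1L, 1L, 0L)),
    "parity-even" = rbind(c(0L, 0L, 0L), c(0L, 1L, 1L), c(1L, 0L, 1L),
                          c(1L, 1L, 0L)),
    "parity-odd"  = rbind(c(0L, 0L, 1L), c(0L, 1L, 0L), c(1L, 0L, 0L),
                          c(1L, 1L, 1L)))
  JointDist(atoms, rep(1 / nrow(atoms), nrow(atoms)), vars = 1:3,
            sizes = c(2L, 2L, 2L))
}

#' Product law of independent variables
#'
#' \code{productLaw} builds the exact joint law of independent variables
#' with the given marginal distributions; \code{independentLaw} is the
#' uniform special case, for which \eqn{H_k = k \log_2 r} on every
#' degree-\eqn{k} face and every \eqn{I_k}, \eqn{k \ge 2}, vanishes.
#'
#' @param marginals list of probability vectors, one per variable.
#' @return a \code{\link{JointDist}}.
#' @export
productLaw <- function(marginals) {
  stopifnot(is.list(marginals), length(marginals) >= 1L)
  sizes <- lengths(marginals)
  if (prod(sizes) > 1e6) stop("product alphabet too large to enumerate")
  grids <- lapply(sizes, function(s) seq_len(s) - 1L)
  atoms <- as.matrix(rev(expand.grid(rev(grids))))
  colnames(atoms) <- NULL
  probs <- apply(atoms, 1L, function(row)
    prod(mapply(function(p, code) p[code + 1L], marginals, row)))
  JointDist(atoms, probs, vars = seq_along(marginals), sizes = sizes)
}

#' @rdname productLaw
#' @param n number of variables; \code{r} alphabet size (\eqn{\ge 2}).
#' @param r alphabet size.
#' @export
independentLaw <- function(n, r) {
  stopifnot(r >= 2L)
  productLaw(rep(list(rep(1 / r, r)), n))
}

#' Sample an i.i.d. uniform independent matrix
#'
#' Draws \eqn{m} samples of \eqn{n} independent variables uniform on
#' \eqn{\{0, \dots, r - 1\}}, returned as a \code{\link{DataMatrix}} of
#' numeric codes (so the standard binning path with \code{N = r}
#' reproduces the codes when all levels are observed).
#'
#' @param n number of variables; \code{r} alphabet size; \code{m} samples.
#' @param r alphabet size.
#' @param m number of samples.
#' @param seed optional RNG seed.
#' @return a \code{DataMatrix}.
#' @export
independentSamples <- function(n, r, m, seed = NULL) {
  stopifnot(r >= 2L, m >= 2L)
  .withSeed(seed, {
    vals <- matrix(sample.int(r, m * n, replace = TRUE) - 1, m, n)
    DataMatrix(vals)
  })
}

#' Joint law of a stationary Markov chain
#'
#' Builds the exact joint distribution of \eqn{n} consecutive states of a
#' homogeneous Markov chain with the given transition kernel, started
#' from its stationary distribution (or \code{init}). On the generating
#' order, every endpoint-joining mutual information collapses to the
#' endpoint pair information (\code{\link{markovConsistency}} holds).
#'
#' @param n chain length (number of variables).
#' @param kernel row-stochastic transition matrix.
#' @param init optional initial distribution; default stationary.
#' @return a \code{\link{JointDist}}.
#' @examples
#' K <- matrix(c(.9, .1, .1, .9), 2, byrow = TRUE)
#' markovConsistency(markovChainLaw(3, K), 1:3)$consistent
#' @export
markovChainLaw <- function(n, kernel, init = NULL) {
  kernel <- as.matrix(kernel)
  r <- nrow(kernel)
  if (ncol(kernel) != r) stop("kernel must be square")
  if (any(kernel < 0) || any(abs(rowSums(kernel) - 1) > 1e-9))
    stop("kernel rows must be probability vectors")
  if (r^n > 1e6) stop("state space too large to enumerate")
  if (is.null(init)) {
    ev <- eigen(t(kernel))
    unit <- which(abs(ev$values - 1) < 1e-9)
    if (length(unit) > 1L) {
      ## reducible kernel (e.g. the identity): stationary law is not
      ## unique; start uniform so every recurrent class is represented
      init <- rep(1 / r, r)
    } else {
      init <- Re(ev$vectors[, unit[1L]])
      init <- init / sum(init)
    }
  }
  grids <- rep(list(seq_len(r) - 1L), n)
  atoms <- as.matrix(rev(expand.grid(rev(grids))))
  colnames(atoms) <- NULL
  probs <- apply(atoms, 1L, function(row) {
    p <- init[row[1L] + 1L]
    for (t in seq_len(n - 1L)) p <- p * kernel[row[t] + 1L, row[t + 1L] + 1L]
    p
  })
  keep <- probs > 0
  JointDist(atoms[keep, , drop = FALSE], probs[keep], vars = seq_len(n),
            sizes = rep(r, n))
}

#' Sample a matrix with one planted dependent module
#'
#' Continuous samples in which the variables of \code{module} are noisy
#' copies of a shared latent uniform source (each entry is replaced by an
#' independent uniform draw with probability \code{copyNoise}) and all
#' remaining variables are independent uniform noise. The module carries
#' the dominant \eqn{I_{|module|}} at large \eqn{m}; with
#' \code{copyNoise = 0} the module variables are exact copies, and as
#' \code{copyNoise} approaches 0.5 the module fades into the independent
#' background. Data are continuous so the full binning path is exercised.
#'
#' @param n number of variables; \code{m} samples.
#' @param m number of samples.
#' @param module integer indices of the planted module.
#' @param copyNoise replacement probability in \eqn{[0, 0.5)}.
#' @param seed optional RNG seed.
#' @return a \code{DataMatrix}.
#' @export
plantedModuleSamples <- function(n, m, module, copyNoise = 0.1, seed = NULL) {
  module <- .assertSubsetOf(module, seq_len(n), "module")
  if (copyNoise < 0 || copyNoise >= 0.5)
    stop("copyNoise must lie in [0, 0.5)")
  .withSeed(seed, {
    latent <- stats::runif(m)
    vals <- matrix(stats::runif(m * n), m, n)
    for (j in module) {
      keep <- stats::runif(m) >= copyNoise
      vals[keep, j] <- latent[keep]
    }
    DataMatrix(vals)
  })
}

#' Sample a two-population design
#'
#' Two disjoint blocks of variables, each a noisy copy of its own latent
#' uniform source, emulating two sub-populations with strong within-block
#' and no cross-block dependence. Optionally one variable of block B is
#' weakly coupled to the block-A source (\code{crossCoupling}), producing
#' a single likely misassignment in path-based classification.
#'
#' @param nPerBlock variables per block (total \eqn{n = 2 \cdot}
#'   \code{nPerBlock}).
#' @param m number of samples.
#' @param blockNoise per-block copy-replacement probabilities, length 2.
#' @param crossCoupling probability that the first block-B variable copies
#'   the block-A source instead of its own (default 0).
#' @param seed optional RNG seed.
#' @return list with \code{data} (a \code{DataMatrix}) and \code{blocks}
#'   (integer vector of block labels 1/2 per variable).
#' @export
twoPopulationSamples <- function(nPerBlock, m, blockNoise = c(0.05, 0.05),
                                 crossCoupling = 0, seed = NULL) {
  stopifnot(nPerBlock >= 2L, m >= 2L, length(blockNoise) == 2L)
  .withSeed(seed, {
    n <- 2L * nPerBlock
    srcA <- stats::runif(m); srcB <- stats::runif(m)
    vals <- matrix(stats::runif(m * n), m, n)
    for (j in seq_len(nPerBlock)) {
      keep <- stats::runif(m) >= blockNoise[1L]
      vals[keep, j] <- srcA[keep]
    }
    for (j in (nPerBlock + 1L):n) {
      src <- srcB
      if (j == nPerBlock + 1L && crossCoupling > 0) {
        mix <- stats::runif(m) < crossCoupling
        src <- ifelse(mix, srcA, srcB)
      }
      keep <- stats::runif(m) >= blockNoise[2L]
      vals[keep, j] <- src[keep]
    }
    list(data = DataMatrix(vals),
         blocks = rep(1:2, each = nPerBlock))
  })
}

#' Uniform draws from a probability simplex
#'
#' Flat-Dirichlet (uniform in affine coordinates) draws of joint laws
#' over the product alphabet described by \code{sizes}, returned as
#' \code{\link{JointDist}} objects. These are the raw material of the
#' algebraic-identity and entropy-bound property checks.
#'
#' @param sizes integer vector of per-variable alphabet sizes (a scalar
#'   is taken as a single variable with that many states).
#' @param count number of draws.
#' @param seed optional RNG seed.
#' @return list of \code{JointDist} objects.
#' @export
simplexDraws <- function(sizes, count, seed = NULL) {
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 2L), count >= 1L)
  S <- prod(sizes)
  grids <- lapply(sizes, function(s) seq_len(s) - 1L)
  atoms <- as.matrix(rev(expand.grid(rev(grids))))
  colnames(atoms) <- NULL
  .withSeed(seed, {
    P <- .flatDirichlet(count, S)
    lapply(seq_len(count), function(i)
      JointDist(atoms, P[i, ], vars = seq_along(sizes), sizes = sizes))
  })
}
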