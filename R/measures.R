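## Information measures on joint distributions.
##
## All quantities are in bits (log base 2), with the convention
## 0 * log 0 = 0. Every measure on a subset of variables depends only on
## the marginal law of that subset (locality), so DiscreteMatrix methods
## first count the empirical joint on the requested variables.
##
## A "subset" argument may be an integer vector (one variable per slot) or
## a list of integer vectors, each element being treated as a single joint
## variable. Grouped slots are what make identities such as the degree-2
## co-cycle relation I2(X;(Y,Z)) + I2(Y;Z) = I2((X,Y);Z) + I2(X;Y)
## expressible.

.asGroups <- function(subset) {
  if (is.list(subset)) lapply(subset, as.integer) else as.list(as.integer(subset))
}

#' @describeIn infoGenerics Shannon entropy of a joint distribution, in
#'   bits. For a distribution with \eqn{s} support atoms,
#'   \eqn{0 \le H \le \log_2 s}.
#' @export
setMethod("shannonEntropy", "JointDist", function(x, ...) {
  .entropyBits(x@probs)
})

## Internal: entropy of the joint variable formed by a union of indices.
.hOf <- function(joint, idx) {
  idx <- sort(unique(as.integer(idx)))
  pos <- match(idx, joint@vars)
  if (anyNA(pos)) stop("variables not present in the distribution")
  keys <- .rowKeys(joint@atoms[, pos, drop = FALSE])
  .entropyBits(as.numeric(rowsum(joint@probs, keys)))
}

#' @describeIn infoGenerics Joint entropy \eqn{H_k} of a subset of
#'   variables: the entropy of their joint law. Monotone under inclusion,
#'   since conditional entropy is non-negative.
#' @export
setMethod("jointEntropy", "JointDist", function(x, subset, ...) {
  groups <- .asGroups(subset)
  if (length(groups) == 0L) stop("subset must be non-empty")
  .hOf(x, unlist(groups))
})

#' @describeIn infoGenerics Joint entropy computed from the empirical
#'   joint of a discrete matrix.
#' @export
setMethod("jointEntropy", "DiscreteMatrix", function(x, subset, ...) {
  u <- sort(unique(unlist(.asGroups(subset))))
  jointEntropy(estimateJoint(x, u), subset)
})

#' Conditional entropy H(target | cond)
#'
#' The average over conditioning outcomes of the entropy of the target
#' conditional laws, weighted by outcome probability; zero-probability
#' branches are dropped. Computed as
#' \eqn{H(\mathrm{target} \cup \mathrm{cond}) - H(\mathrm{cond})}, to which
#' the branch average is identically equal. Always non-negative.
#'
#' @param x a \code{\link{JointDist}} or \code{\link{DiscreteMatrix}}.
#' @param target,cond disjoint variable subsets (integer vectors, or lists
#'   of integer vectors for grouped joint variables).
#' @return conditional entropy in bits.
#' @export
conditionalEntropy <- function(x, target, cond) {
  tU <- unlist(.asGroups(target)); cU <- unlist(.asGroups(cond))
  if (length(intersect(tU, cU)) > 0L)
    stop("target and conditioning subsets must be disjoint")
  if (is(x, "DiscreteMatrix")) x <- estimateJoint(x, sort(unique(c(tU, cU))))
  stopifnot(is(x, "JointDist"))
  .hOf(x, c(tU, cU)) - .hOf(x, cU)
}

## Internal: alternating entropy sum over the sub-subsets of a list of
## groups, optionally with every term conditioned on `condIdx` (the
## conditional average of Ik equals the same alternating sum of
## conditional entropies, by linearity of the conditional average).
.ikGroups <- function(joint, groups, condIdx = integer(0)) {
  k <- length(groups)
  hc <- if (length(condIdx)) .hOf(joint, condIdx) else 0
  total <- 0
  for (r in seq_len(k)) {
    cmb <- utils::combn(k, r)
    sgn <- (-1)^(r - 1)
    for (j in seq_len(ncol(cmb))) {
      u <- c(unlist(groups[cmb[, j]]), condIdx)
      total <- total + sgn * (.hOf(joint, u) - hc)
    }
  }
  total
}

#' @describeIn infoGenerics Multivariate mutual information \eqn{I_k}: the
#'   alternating sum of the joint entropies of every non-empty sub-subset.
#'   \eqn{I_1 = H}; \eqn{I_2 \ge 0}; \eqn{I_k} may be negative for
#'   \eqn{k \ge 3}. Symmetric under permutations of the subset.
#' @export
setMethod("mutualInfo", "JointDist", function(x, subset, ...) {
  groups <- .asGroups(subset)
  if (length(groups) == 0L) stop("subset must be non-empty")
  u <- unlist(groups)
  if (anyDuplicated(u)) stop("groups must not share variables")
  .ikGroups(x, groups)
})

#' @describeIn infoGenerics \eqn{I_k} computed from the empirical joint of
#'   a discrete matrix.
#' @export
setMethod("mutualInfo", "DiscreteMatrix", function(x, subset, ...) {
  u <- sort(unique(unlist(.asGroups(subset))))
  mutualInfo(estimateJoint(x, u), subset)
})

#' Conditional mutual information
#'
#' The probability-weighted average of \eqn{I_k} on the target subset over
#' the outcomes of the conditioning joint variable. Satisfies the chain
#' relation \eqn{I_{k+1}(X_0; X_1; \dots; X_k) = I_k(X_1; \dots; X_k) -
#' X_0.I_k(X_1; \dots; X_k)}, which is also how information-path slopes
#' arise.
#'
#' @param x a \code{\link{JointDist}} or \code{\link{DiscreteMatrix}}.
#' @param subset variable subset (or list of groups) whose \eqn{I_k} is
#'   averaged.
#' @param cond conditioning variables, disjoint from \code{subset};
#'   conditioning is on their joint outcome.
#' @return conditional mutual information in bits.
#' @export
conditionalMutualInfo <- function(x, subset, cond) {
  groups <- .asGroups(subset)
  condIdx <- unlist(.asGroups(cond))
  u <- unlist(groups)
  if (length(intersect(u, condIdx)) > 0L)
    stop("subset and conditioning variables must be disjoint")
  if (is(x, "DiscreteMatrix"))
    x <- estimateJoint(x, sort(unique(c(u, condIdx))))
  stopifnot(is(x, "JointDist"))
  .ikGroups(x, groups, condIdx)
}

#' @describeIn infoGenerics Total correlation (multi-information)
#'   \eqn{G_k = \sum_i H(X_i) - H(X_1, \dots, X_k)}: non-negative, zero
#'   exactly when the variables are independent, and \eqn{G_2 = I_2}.
#' @export
setMethod("totalCorrelation", "JointDist", function(x, subset, ...) {
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  sum(vapply(subset, function(v) .hOf(x, v), numeric(1))) - .hOf(x, subset)
})

#' @describeIn infoGenerics Total correlation from the empirical joint of
#'   a discrete matrix.
#' @export
setMethod("totalCorrelation", "DiscreteMatrix", function(x, subset, ...) {
  totalCorrelation(estimateJoint(x, as.integer(subset)), as.integer(subset))
})

#' Eta decomposition value of a face
#'
#' \eqn{\eta_J} is the degree-\eqn{|J|} mutual information of the face
#' \eqn{J} conditioned on the joint of all remaining variables of the
#' distribution (empty conditioning when \eqn{J} is the full set, so
#' \eqn{\eta_{[n]} = I_n}). The eta values additively reassemble every
#' measure: \eqn{I_k(X_I) = \sum_{J \supseteq I} \eta_J} and
#' \eqn{H_k(X_I) = \sum_{J \cap I \neq \emptyset} \eta_J}.
#'
#' @param x a \code{\link{JointDist}} over the full variable set.
#' @param J non-empty integer subset of \code{x@vars}.
#' @return eta value in bits.
#' @export
etaValue <- function(x, J) {
  stopifnot(is(x, "JointDist"))
  J <- .assertSubsetOf(J, x@vars, "J")
  comp <- setdiff(x@vars, J)
  if (length(comp) == 0L) mutualInfo(x, J)
  else conditionalMutualInfo(x, as.list(J), comp)
}

#' Eta value by Moebius inversion of an entropy landscape
#'
#' Recovers \eqn{\eta_J} from a complete joint-entropy table by
#' inclusion-exclusion. Inverting the superset decomposition
#' \eqn{I_k(X_I) = \sum_{J \supseteq I} \eta_J} over the lattice and
#' expanding each \eqn{I_k} in joint entropies collapses to
#' \deqn{\eta_J = \sum_{A \subseteq J} (-1)^{|A|+1}
#'       H(X_{A \cup ([n] \setminus J)}),}
#' the sum running over the faces containing the complement of \eqn{J}
#' (the empty face contributes nothing). For \eqn{J = [n]} this is the
#' usual inclusion-exclusion for \eqn{I_n}; for \eqn{n = 2, J = \{1,2\}}
#' it reduces to \eqn{H(X_1) + H(X_2) - H(X_1, X_2) = I_2}. Agrees with
#' \code{\link{etaValue}} computed by conditioning.
#'
#' @param landscape an \code{InfoLandscape} of measure \code{"H"} complete
#'   up to degree \code{n} (every face containing the complement of
#'   \code{J} must be present).
#' @param J non-empty integer subset of \code{1:n}.
#' @return eta value in bits.
#' @export
etaFromEntropies <- function(landscape, J) {
  stopifnot(is(landscape, "InfoLandscape"))
  if (landscape@measure != "H") stop("an H landscape is required")
  J <- .assertSubsetOf(J, seq_len(landscape@n), "J")
  comp <- setdiff(seq_len(landscape@n), J)
  total <- 0
  for (r in 0:length(J)) {
    subsetsA <- if (r == 0L) list(integer(0)) else .combnList(J, r)
    for (a in subsetsA) {
      face <- c(comp, a)
      if (length(face) == 0L) next
      key <- .faceKey(face)
      i <- match(key, landscape@keys)
      if (is.na(i))
        stop("landscape is missing face {", key, "}")
      total <- total + (-1)^(r + 1) * landscape@values[i]
    }
  }
  total
}
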