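# Independent oracles, deliberately written against the definitions and
# not sharing code paths with the package implementation.

# Entropy by direct summation over a dense probability vector.
oracleEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Conditional entropy by explicit branch averaging: enumerate the
# outcomes of the conditioning variables, condition, weight by outcome
# probability (zero-mass branches never occur in the sparse support).
oracleCondEntropy <- function(joint, target, cond) {
  pos <- match(cond, joint@vars)
  keys <- apply(joint@atoms[, pos, drop = FALSE], 1L, paste, collapse = ",")
  total <- 0
  for (key in unique(keys)) {
    hit <- keys == key
    w <- sum(joint@probs[hit])
    outcome <- joint@atoms[which(hit)[1L], pos]
    cj <- conditionOn(joint, cond, outcome)
    total <- total + w * jointEntropy(cj, target)
  }
  total
}

# Ik by recursion on the chain relation
# I_{k+1}(v0; rest) = I_k(rest) - v0.I_k(rest),
# with the conditional average evaluated branch by branch. Independent of
# the alternating-entropy-sum route used by the package.
oracleIk <- function(joint, subset) {
  subset <- as.integer(subset)
  if (length(subset) == 1L)
    return(shannonEntropy(marginalize(joint, subset)))
  v0 <- subset[1L]
  rest <- subset[-1L]
  base <- oracleIk(joint, rest)
  pos <- match(v0, joint@vars)
  condAvg <- 0
  for (code in unique(joint@atoms[, pos])) {
    hit <- joint@atoms[, pos] == code
    w <- sum(joint@probs[hit])
    condAvg <- condAvg + w * oracleIk(conditionOn(joint, v0, code), rest)
  }
  base - condAvg
}

# Conditional Ik by branch averaging over the joint conditioning outcome.
oracleCondIk <- function(joint, subset, cond) {
  pos <- match(cond, joint@vars)
  keys <- apply(joint@atoms[, pos, drop = FALSE], 1L, paste, collapse = ",")
  total <- 0
  for (key in unique(keys)) {
    hit <- keys == key
    w <- sum(joint@probs[hit])
    outcome <- joint@atoms[which(hit)[1L], pos]
    total <- total + w * oracleIk(conditionOn(joint, cond, outcome), subset)
  }
  total
}

# Random joints on a product alphabet via the package's simplex sampler
# (its output is itself property-tested in test-fixtures.R).
randomJoints <- function(sizes, count, seed) {
  simplexDraws(sizes, count, seed = seed)
}

# Probabilities of a joint as a named vector keyed by atom, for
# order-insensitive comparison.
jointAsVector <- function(joint) {
  pt <- probTable(joint)
  stats::setNames(pt$prob, pt$atom)
}

expectSameLaw <- function(a, b, tol = 1e-12) {
  va <- jointAsVector(a); vb <- jointAsVector(b)
  expect_setequal(names(va), names(vb))
  expect_equal(va[sort(names(va))], vb[sort(names(vb))], tolerance = tol)
}

# Deterministic parity (XOR) samples: each even-parity tuple repeated
# `rep` times, so the empirical law is exactly the parity distribution.
xorSamples <- function(rep = 25L) {
  tuples <- rbind(c(0, 0, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))
  vals <- tuples[rep(seq_len(4L), each = rep), ]
  DataMatrix(vals)
}
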