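test_that("entropy matches closed forms", {
  coin <- JointDist(rbind(0L, 1L), c(0.5, 0.5))
  expect_equal(shannonEntropy(coin), 1)
  point <- JointDist(rbind(0L), 1, sizes = 2L)
  expect_equal(shannonEntropy(point), 0)
  unif9 <- JointDist(matrix(0:8, ncol = 1), rep(1 / 9, 9))
  expect_equal(shannonEntropy(unif9), log2(9))
})

test_that("joint entropies match closed forms and are monotone", {
  xor <- extremalTriple("parity-even")
  expect_equal(jointEntropy(xor, 1:3), 2)
  expect_equal(jointEntropy(xor, c(1, 2)), 2)
  expect_equal(jointEntropy(xor, 1L), 1)

  copyPair <- JointDist(rbind(c(0L, 0L), c(1L, 1L)), c(0.5, 0.5))
  expect_equal(jointEntropy(copyPair, 1:2), 1)
  indepPair <- productLaw(list(c(.5, .5), c(.5, .5)))
  expect_equal(jointEntropy(indepPair, 1:2), 2)

  for (j in randomJoints(c(2, 3, 2), 5, seed = 5)) {
    expect_gte(jointEntropy(j, 1:2) + 1e-12, jointEntropy(j, 1L))
    expect_gte(jointEntropy(j, 1:3) + 1e-12, jointEntropy(j, 1:2))
  }
})

test_that("conditional entropy equals the branch average and behaves", {
  for (j in randomJoints(c(2, 2, 3), 6, seed = 9)) {
    expect_equal(conditionalEntropy(j, 3L, c(1L, 2L)),
                 oracleCondEntropy(j, 3L, c(1L, 2L)), tolerance = 1e-10)
    expect_gte(conditionalEntropy(j, 1L, c(2L, 3L)), -1e-12)
  }
  indep <- productLaw(list(c(.3, .7), c(.5, .5)))
  expect_equal(conditionalEntropy(indep, 1L, 2L),
               jointEntropy(indep, 1L), tolerance = 1e-12)
  copyPair <- JointDist(rbind(c(0L, 0L), c(1L, 1L)), c(.5, .5))
  expect_equal(conditionalEntropy(copyPair, 1L, 2L), 0, tolerance = 1e-12)
  expect_error(conditionalEntropy(copyPair, 1L, 1L), "disjoint")
})

test_that("mutual information matches closed forms on extremal triples", {
  expect_equal(mutualInfo(extremalTriple("identical"), 1:3), 1)
  expect_equal(mutualInfo(extremalTriple("opposite2"), 1:3), 1)
  expect_equal(mutualInfo(extremalTriple("parity-even"), 1:3), -1)
  expect_equal(mutualInfo(extremalTriple("parity-odd"), 1:3), -1)

  indep <- productLaw(list(c(.2, .8), c(.6, .4)))
  expect_equal(mutualInfo(indep, 1:2), 0, tolerance = 1e-12)

  biased <- JointDist(rbind(c(0L, 0L), c(1L, 1L)), c(.3, .7))
  expect_equal(mutualInfo(biased, 1:2), shannonEntropy(biased))
})

test_that("Ik agrees with the recursive chain-rule oracle", {
  for (j in randomJoints(c(2, 2, 2), 6, seed = 21)) {
    expect_equal(mutualInfo(j, 1:3), oracleIk(j, 1:3), tolerance = 1e-10)
  }
  for (j in randomJoints(c(2, 3, 2, 2), 3, seed = 22)) {
    expect_equal(mutualInfo(j, 1:4), oracleIk(j, 1:4), tolerance = 1e-10)
    expect_equal(mutualInfo(j, c(2, 4)), oracleIk(j, c(2, 4)),
                 tolerance = 1e-10)
  }
})

test_that("Ik is permutation symmetric and I2 non-negative", {
  for (j in randomJoints(c(2, 2, 3), 6, seed = 13)) {
    expect_equal(mutualInfo(j, c(1, 2, 3)), mutualInfo(j, c(3, 1, 2)),
                 tolerance = 1e-12)
    expect_gte(mutualInfo(j, c(1, 3)), -1e-10)
  }
})

test_that("conditional mutual information satisfies the chain relations", {
  xor <- extremalTriple("parity-even")
  ## conditioning creates dependence in the Borromean configuration
  expect_equal(conditionalMutualInfo(xor, c(1, 2), 3), 1, tolerance = 1e-12)
  expect_equal(mutualInfo(xor, 1:3),
               mutualInfo(xor, c(1, 2)) - conditionalMutualInfo(xor, c(1, 2), 3),
               tolerance = 1e-12)

  indep <- productLaw(list(c(.5, .5), c(.3, .7), c(.5, .5)))
  expect_equal(conditionalMutualInfo(indep, c(1, 2), 3), 0, tolerance = 1e-12)

  for (j in randomJoints(c(2, 2, 2, 2), 6, seed = 31)) {
    ## I_{k+1}(X0;...) = Ik(rest) - X0.Ik(rest)
    expect_equal(mutualInfo(j, 1:4),
                 mutualInfo(j, 2:4) - conditionalMutualInfo(j, 2:4, 1),
                 tolerance = 1e-10)
    ## branch-average oracle
    expect_equal(conditionalMutualInfo(j, c(2, 3), c(1, 4)),
                 oracleCondIk(j, c(2, 3), c(1, 4)), tolerance = 1e-10)
    ## joint-variable expansion Ik((X0,X1);X2;..) = Ik(X0;X2;..) + X0.Ik(X1;X2;..)
    expect_equal(mutualInfo(j, list(c(1, 2), 3, 4)),
                 mutualInfo(j, list(1, 3, 4)) +
                   conditionalMutualInfo(j, list(2, 3, 4), 1),
                 tolerance = 1e-10)
  }
})

test_that("degree-2 information is a co-cycle but not additive over joints", {
  for (j in randomJoints(c(2, 3, 2), 6, seed = 41)) {
    lhs <- mutualInfo(j, list(1, c(2, 3))) + mutualInfo(j, c(2, 3))
    rhs <- mutualInfo(j, list(c(1, 2), 3)) + mutualInfo(j, c(1, 2))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  ## additivity fails in general: parity witness
  xor <- extremalTriple("parity-even")
  expect_equal(mutualInfo(xor, list(1, c(2, 3))), 1, tolerance = 1e-12)
  expect_equal(mutualInfo(xor, c(1, 2)) + mutualInfo(xor, c(1, 3)), 0,
               tolerance = 1e-12)
})

test_that("the Ik table inverts back to the joint entropy", {
  for (j in randomJoints(c(2, 2, 3), 5, seed = 51)) {
    faces <- enumerateFaces(3, 3)
    total <- 0
    for (f in faces) total <- total + (-1)^(length(f) - 1) * mutualInfo(j, f)
    expect_equal(total, jointEntropy(j, 1:3), tolerance = 1e-10)
  }
})

test_that("total correlation is non-negative, zero iff independent, and G2 = I2", {
  indep <- productLaw(list(c(.2, .8), c(.5, .5), c(.4, .6)))
  expect_equal(totalCorrelation(indep, 1:3), 0, tolerance = 1e-12)
  for (j in randomJoints(c(2, 2, 2), 6, seed = 61)) {
    expect_gte(totalCorrelation(j, 1:3), -1e-10)
    expect_equal(totalCorrelation(j, c(1, 3)), mutualInfo(j, c(1, 3)),
                 tolerance = 1e-12)
  }
  ## k identical unbiased bits: Gk = k - 1
  for (k in 2:4) {
    atoms <- rbind(rep(0L, k), rep(1L, k))
    ident <- JointDist(atoms, c(.5, .5))
    expect_equal(totalCorrelation(ident, seq_len(k)), k - 1)
  }
})

test_that("eta values decompose entropies and informations", {
  single <- JointDist(rbind(0L, 1L), c(.3, .7))
  expect_equal(etaValue(single, 1L), shannonEntropy(single))

  xor <- extremalTriple("parity-even")
  expect_equal(etaValue(xor, 1:3), -1, tolerance = 1e-12)

  for (j in randomJoints(c(2, 2, 2), 5, seed = 71)) {
    faces <- enumerateFaces(3, 3)
    etas <- vapply(faces, function(f) etaValue(j, f), numeric(1))
    keys <- vapply(faces, function(f) paste(sort(f), collapse = ";"),
                   character(1))
    names(etas) <- keys
    ## sum over all faces recovers H3
    expect_equal(sum(etas), jointEntropy(j, 1:3), tolerance = 1e-10)
    ## Ik(I) = sum of eta over supersets of I
    for (f in faces) {
      supers <- Filter(function(g) all(f %in% g), faces)
      expect_equal(mutualInfo(j, f),
                   sum(etas[vapply(supers, function(g)
                     paste(sort(g), collapse = ";"), character(1))]),
                   tolerance = 1e-10)
    }
    ## Hk(I) = sum of eta over faces meeting I
    for (f in faces) {
      touching <- Filter(function(g) length(intersect(f, g)) > 0, faces)
      expect_equal(jointEntropy(j, f),
                   sum(etas[vapply(touching, function(g)
                     paste(sort(g), collapse = ";"), character(1))]),
                   tolerance = 1e-10)
    }
  }
})

test_that("Moebius inversion of the entropy table reproduces eta", {
  ## two variables: eta_{12} = H1 + H2 - H12 = I2
  pair <- randomJoints(c(2, 3), 1, seed = 81)[[1]]
  dmH <- new("InfoLandscape", measure = "H", n = 2L, kmax = 2L,
             keys = c("1", "2", "1;2"), degrees = c(1L, 1L, 2L),
             values = c(jointEntropy(pair, 1), jointEntropy(pair, 2),
                        jointEntropy(pair, 1:2)),
             metadata = list())
  expect_equal(etaFromEntropies(dmH, 1:2), mutualInfo(pair, 1:2),
               tolerance = 1e-12)

  for (j in randomJoints(c(2, 2, 2), 4, seed = 82)) {
    faces <- enumerateFaces(3, 3)
    keys <- vapply(faces, function(f) paste(f, collapse = ";"), character(1))
    hl <- new("InfoLandscape", measure = "H", n = 3L, kmax = 3L,
              keys = keys, degrees = lengths(faces),
              values = vapply(faces, function(f) jointEntropy(j, f),
                              numeric(1)),
              metadata = list())
    for (f in faces)
      expect_equal(etaFromEntropies(hl, f), etaValue(j, f),
                   tolerance = 1e-10)
  }
  xorKeys <- enumerateFaces(3, 3)
  xor <- extremalTriple("parity-even")
  hl <- new("InfoLandscape", measure = "H", n = 3L, kmax = 3L,
            keys = vapply(xorKeys, function(f) paste(f, collapse = ";"),
                          character(1)),
            degrees = lengths(xorKeys),
            values = vapply(xorKeys, function(f) jointEntropy(xor, f),
                            numeric(1)), metadata = list())
  expect_equal(etaFromEntropies(hl, 1:3), -1, tolerance = 1e-12)
})

test_that("information bounds hold on random laws", {
  for (j in randomJoints(c(2, 2, 2), 10, seed = 91)) {
    h <- vapply(1:3, function(v) jointEntropy(j, v), numeric(1))
    i2 <- mutualInfo(j, c(1, 2))
    expect_gte(i2, -1e-10)
    expect_lte(i2, min(h[1], h[2]) + 1e-10)
    i3 <- mutualInfo(j, 1:3)
    expect_lte(abs(i3), min(h) + 1e-10)
  }
})

test_that("measures are local: marginal and full-joint routes agree", {
  for (j in randomJoints(c(2, 3, 2, 2), 4, seed = 101)) {
    S <- c(1, 3, 4)
    mj <- marginalize(j, S)
    expect_equal(mutualInfo(j, S), mutualInfo(mj, S), tolerance = 1e-12)
    expect_equal(jointEntropy(j, S), jointEntropy(mj, S), tolerance = 1e-12)
    expect_equal(totalCorrelation(j, S), totalCorrelation(mj, S),
                 tolerance = 1e-12)
  }
})

test_that("Markov chains satisfy the endpoint-collapse criterion, parity does not", {
  K <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
  chain <- markovChainLaw(3, K)
  expect_true(markovConsistency(chain, 1:3)$consistent)
  expect_equal(mutualInfo(chain, 1:3), mutualInfo(chain, c(1, 3)),
               tolerance = 1e-10)
  xor <- extremalTriple("parity-even")
  mk <- markovConsistency(xor, 1:3)
  expect_false(mk$consistent)
})
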