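test_that("face enumeration has the binomial counts in (degree, lex) order", {
  f3 <- enumerateFaces(3, 3)
  expect_length(f3, 7L)
  expect_equal(f3[[1]], 1L)
  expect_equal(f3[[4]], c(1L, 2L))
  expect_equal(f3[[7]], 1:3)
  expect_length(enumerateFaces(21, 2), 21L + 210L)
  expect_equal(sum(lengths(enumerateFaces(21, 3)) == 3L), 1330L)
  expect_error(enumerateFaces(3, 4), "kmax")
})

test_that("landscapes of the uniform independent law match the null sequences", {
  ## samples listing every tuple once realise the exact product law
  r <- 2L; n <- 3L
  tuples <- as.matrix(expand.grid(0:(r - 1), 0:(r - 1), 0:(r - 1)))
  colnames(tuples) <- NULL
  dm <- discretize(DataMatrix(tuples), N = r)
  lsH <- computeLandscape(dm, "H", kmax = 3)
  lsI <- computeLandscape(dm, "I", kmax = 3)
  for (k in 1:3) {
    expect_equal(unique(round(lsH@values[lsH@degrees == k], 12)),
                 k * log2(r))
    if (k >= 2)
      expect_equal(max(abs(lsI@values[lsI@degrees == k])), 0,
                   tolerance = 1e-12)
    else
      expect_equal(unique(round(lsI@values[lsI@degrees == 1], 12)), log2(r))
  }
})

test_that("empirical parity samples reproduce the synergistic landscape entry", {
  dm <- discretize(xorSamples(25L), N = 2)
  lsI <- computeLandscape(dm, "I", kmax = 3)
  expect_equal(faceValue(lsI, 1:3), -1, tolerance = 1e-12)
  expect_equal(faceValue(lsI, c(1, 2)), 0, tolerance = 1e-12)
  ## landscape values agree with direct measure calls (locality)
  expect_equal(faceValue(lsI, 1:3), mutualInfo(dm, 1:3), tolerance = 1e-12)
})

test_that("mean paths average each degree and require completeness", {
  dm <- discretize(independentSamples(4, 3, 50, seed = 2), N = 3)
  ls <- computeLandscape(dm, "I", kmax = 3)
  mp <- meanPath(ls)
  tab <- landscapeTable(ls)
  for (k in 1:3)
    expect_equal(unname(mp[k]), mean(tab$value[tab$degree == k]),
                 tolerance = 1e-12)
  ## a single-variable landscape: mean path is H(X1)
  one <- DataMatrix(cbind(v = c(0, 0, 1, 1)))
  ls1 <- computeLandscape(discretize(one, N = 2), "H", kmax = 1)
  expect_equal(unname(meanPath(ls1)), 1)
  ## incomplete landscape rejected
  broken <- ls
  broken@keys <- ls@keys[-1]; broken@values <- ls@values[-1]
  broken@degrees <- ls@degrees[-1]
  expect_error(meanPath(broken), "incomplete")
})

test_that("maxTuple returns the extremal face with lexicographic ties", {
  dm <- discretize(xorSamples(10L), N = 2)
  lsI <- computeLandscape(dm, "I", kmax = 3)
  expect_equal(maxTuple(lsI, 3, "min"), 1:3)
  ## all-equal entries at a degree: lexicographically smallest face wins
  expect_equal(maxTuple(lsI, 2, "max"), c(1L, 2L))
})

test_that("the planted module carries the extremal face and the max path", {
  x <- plantedModuleSamples(8, 1500, module = c(2, 4, 5, 7),
                            copyNoise = 0.1, seed = 19)
  dm <- discretize(x, N = 3)
  lsI <- computeLandscape(dm, "I", kmax = 4)
  expect_equal(maxTuple(lsI, 4, "max"), c(2L, 4L, 5L, 7L))
  pth <- extremalPaths(dm, "max", kmax = 6)[[1]]
  expect_setequal(pathVariables(pth)[1:4], c(2, 4, 5, 7))
})

test_that("greedy paths match exhaustive search on planted-module data", {
  x <- plantedModuleSamples(7, 800, module = 1:4, copyNoise = 0.05,
                            seed = 23)
  dm <- discretize(x, N = 3)
  g <- extremalPaths(dm, "max", kmax = 7, search = "greedy")
  e <- extremalPaths(dm, "max", kmax = 7, search = "exhaustive")
  expect_gte(length(e), 1L)
  ## greedy cannot beat exhaustive; on this fixture they coincide
  expect_equal(length(pathVariables(g[[1]])), length(pathVariables(e[[1]])))
  expect_equal(pathValues(g[[1]])[length(pathValues(g[[1]]))],
               pathValues(e[[1]])[length(pathValues(e[[1]]))],
               tolerance = 1e-12)
})

test_that("independent data stop the maximal path at the first minimum", {
  r <- 2L
  tuples <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  colnames(tuples) <- NULL
  dm <- discretize(DataMatrix(tuples), N = r)
  paths <- extremalPaths(dm, "max", kmax = 4)
  expect_equal(length(pathVariables(paths[[1]])), 2L)
  expect_equal(paths[[1]]@stopReason, "first-minimum")
})

test_that("path values are consistent with landscape prefix faces and H is monotone", {
  x <- plantedModuleSamples(6, 300, module = 1:3, copyNoise = 0.1, seed = 29)
  dm <- discretize(x, N = 3)
  lsI <- computeLandscape(dm, "I", kmax = 6)
  lsH <- computeLandscape(dm, "H", kmax = 6)
  for (p in extremalPaths(dm, "max", kmax = 6)) {
    vars <- pathVariables(p)
    vals <- pathValues(p)
    hPrev <- -Inf
    for (k in seq_along(vars)) {
      expect_equal(vals[k], faceValue(lsI, vars[1:k]), tolerance = 1e-12)
      hk <- faceValue(lsH, vars[1:k])
      expect_gte(hk, hPrev - 1e-12)
      hPrev <- hk
    }
  }
})

test_that("two separated blocks are recovered as two longest path components", {
  tp <- twoPopulationSamples(4, 800, blockNoise = c(0.05, 0.05), seed = 37)
  dm <- discretize(tp$data, N = 3)
  ## cap the paths at the block size: beyond its block a path keeps
  ## falling through near-zero information and mixes supports
  paths <- extremalPaths(dm, "max", kmax = 4, search = "exhaustive")
  comps <- pathComponents(paths)
  expect_gte(length(comps), 2L)
  expect_setequal(comps[[1]], which(tp$blocks == tp$blocks[comps[[1]][1]]))
  expect_setequal(sort(unlist(comps[1:2])), 1:8)
})

test_that("landscape sweep reduces to the direct mean path at full sample", {
  x <- independentSamples(4, 2, 60, seed = 41)
  sweep <- landscapeSweep(x, NList = 2, mList = c(30, 60), kmax = 3,
                          seed = 43)
  direct <- meanPath(computeLandscape(discretize(x, N = 2), "I", kmax = 3))
  full <- sweep[sweep$m == 60, ]
  expect_equal(full$mean, unname(direct), tolerance = 1e-12)
  ## independent bits: near-null mean information beyond degree 1
  expect_lt(max(abs(sweep$mean[sweep$degree > 1])), 0.15)
  crit <- attr(sweep, "criticalDim")
  expect_equal(nrow(crit), 2L)
  ## two seeds agree within sampling error on independent data
  s2 <- landscapeSweep(x, NList = 2, mList = 30, kmax = 3, seed = 97)
  expect_lt(max(abs(s2$mean[s2$degree > 1] -
                    sweep$mean[sweep$degree > 1 & sweep$m == 30])), 0.3)
  expect_error(landscapeSweep(x, 2, mList = 100), "exceed")
})

test_that("the face-count guard and kmax>ku warning fire", {
  dm <- discretize(independentSamples(10, 2, 20, seed = 3), N = 2)
  expect_error(computeLandscape(dm, "H", kmax = 6, maxFaces = 100), "faces")
  expect_warning(computeLandscape(dm, "H", kmax = 3, ku = 2), "undersampling")
})
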