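test_that("fitness evaluation reproduces the Fourier sum on the toy map", {
  T1 <- toyMap()
  expect_equal(evaluateFitness(T1, c(1, 1)), 1.4)
  expect_equal(evaluateFitness(T1, c(-1, 1)), 0)
  expect_equal(evaluateFitness(fourierLandscape(3, baseline = 2.5),
                               c(-1, 1, -1)), 2.5)
  G <- enumerateGenotypes(2)
  expect_equal(evaluateFitness(T1, G),
               apply(G, 1, function(g) evaluateFitness(T1, g)))
})

test_that("fitness evaluation matches an independent plain-R oracle", {
  set.seed(101)
  for (r in 1:10) {
    l <- sample(3:9, 1)
    ls <- randomSparseLandscape(l, baseline = rnorm(1))
    g <- randomGenotypes(1, l)[1, ]
    expect_equal(evaluateFitness(ls, g),
                 naiveFitness(l, baseline(ls), landscapeTerms(ls),
                              landscapeCoefs(ls), g),
                 tolerance = 1e-12)
  }
})

test_that("mutation effects equal fitness differences and are involutive", {
  T1 <- toyMap()
  expect_equal(mutationEffect(T1, c(-1, 1), 1), 1.4)
  expect_equal(mutationEffect(T1, c(1, -1), 2), -0.2)
  set.seed(102)
  for (r in 1:10) {
    l <- sample(3:9, 1)
    ls <- randomSparseLandscape(l)
    g <- randomGenotypes(1, l)[1, ]
    i <- sample.int(l, 1)
    g2 <- g
    g2[i] <- -g2[i]
    s <- mutationEffect(ls, g, i)
    expect_equal(s, evaluateFitness(ls, g2) - evaluateFitness(ls, g),
                 tolerance = 1e-12)
    expect_equal(mutationEffect(ls, g2, i), -s, tolerance = 1e-12)
    expect_equal(allMutationEffects(ls, g)[i], s, tolerance = 1e-12)
  }
})

test_that("total variance and baseline equal enumeration moments", {
  set.seed(103)
  for (r in 1:5) {
    l <- sample(3:8, 1)
    ls <- randomSparseLandscape(l, baseline = rnorm(1))
    y <- evaluateFitness(ls, enumerateGenotypes(l))
    expect_equal(mean(y), baseline(ls), tolerance = 1e-10)
    expect_equal(mean((y - mean(y))^2), totalVariance(ls), tolerance = 1e-10)
  }
})

test_that("variance fractions follow the coefficient-table definition", {
  T1 <- toyMap()
  expect_equal(varianceFraction(T1, 1), 0.29 / 0.38)
  expect_equal(varianceFraction(T1, 2), 0.13 / 0.38)
  expect_equal(varianceFractions(T1), c(0.29, 0.13) / 0.38)
  # cross-check against the flip-correlation identity v = (1 - r)/2
  G <- enumerateGenotypes(2)
  y <- evaluateFitness(T1, G)
  yf <- y + apply(G, 1, function(g) mutationEffect(T1, g, 1))
  r <- sum((y - mean(y)) * (yf - mean(yf))) / sum((y - mean(y))^2)
  expect_equal(varianceFraction(T1, 1), (1 - r) / 2)
  # purely additive landscape with equal |f|: v_i = 1/l
  add <- fourierLandscape(5, 0, as.list(1:5), c(1, -1, 1, -1, 1) * 0.3)
  expect_equal(varianceFractions(add), rep(0.2, 5))
  expect_error(varianceFraction(fourierLandscape(2), 1), "zero total")
})

test_that("directed VF matches the subcube regression in both directions", {
  T1 <- toyMap()
  expect_equal(directedVF(T1, 1), 0.4)
  expect_equal(directedVF(T1, 2), -0.10 / 0.15)
  set.seed(104)
  for (r in 1:8) {
    l <- sample(3:8, 1)
    ls <- randomSparseLandscape(l)
    i <- sample.int(l, 1)
    G <- enumerateGenotypes(l)
    for (dir in c("up", "down")) {
      sub <- G[G[, i] == (if (dir == "up") -1 else 1), , drop = FALSE]
      y <- evaluateFitness(ls, sub)
      s <- apply(sub, 1, function(g) mutationEffect(ls, g, i))
      expect_equal(directedVF(ls, i, dir), -popOLS(y, s)$slope / 2,
                   tolerance = 1e-9)
    }
  }
  # a locus with no epistatic terms has directed VF 0
  ls <- fourierLandscape(3, 0, list(1, 2, c(2, 3)), c(0.4, 0.2, 0.3))
  expect_equal(directedVF(ls, 1), 0)
})

test_that("pairwise and double-mutant VFs agree with enumeration", {
  T1 <- toyMap()
  expect_equal(pairEpistaticVF(T1, 1, 2), 0.04 / 0.38)
  expect_equal(pairEpistaticVF(T1, 1, 1), varianceFraction(T1, 1))
  expect_equal(doubleMutantVF(T1, 1, 2), 0.29 / 0.38 + 0.13 / 0.38 - 0.08 / 0.38)
  expect_error(doubleMutantVF(T1, 1, 1), "distinct")
  add <- fourierLandscape(4, 0, as.list(1:4), rnorm(4))
  expect_equal(pairEpistaticVF(add, 1, 3), 0)
  expect_equal(doubleMutantVF(add, 1, 3),
               sum(varianceFraction(add, c(1, 3))))
  set.seed(105)
  for (r in 1:8) {
    l <- sample(3:8, 1)
    ls <- randomSparseLandscape(l)
    ij <- sample.int(l, 2)
    G <- enumerateGenotypes(l)
    y <- evaluateFitness(ls, G)
    s <- apply(G, 1, function(g) jointFlipEffect(ls, g, ij))
    expect_equal(popOLS(y, s)$slope, -2 * doubleMutantVF(ls, ij[1], ij[2]),
                 tolerance = 1e-9)
    expect_equal(jointVF(ls, ij), doubleMutantVF(ls, ij[1], ij[2]),
                 tolerance = 1e-12)
  }
})

test_that("joint and cross VFs treat multi-locus flips as one perturbation", {
  set.seed(106)
  ls <- randomSparseLandscape(7)
  loci <- c(2, 4, 6)
  G <- enumerateGenotypes(7)
  y <- evaluateFitness(ls, G)
  s <- apply(G, 1, function(g) jointFlipEffect(ls, g, loci))
  expect_equal(popOLS(y, s)$slope, -2 * jointVF(ls, loci), tolerance = 1e-9)
  # e_{i, J} recovers v_i + v_J - 2 e = VF of the combined flip
  i <- 1
  expect_equal(jointVF(ls, c(i, loci)),
               varianceFraction(ls, i) + jointVF(ls, loci) -
                 2 * crossEpistaticVF(ls, i, loci),
               tolerance = 1e-12)
})

test_that("AoIL and additivity match their defining ratios", {
  T1 <- toyMap()
  expect_equal(aoil(T1, 1), 0.6)
  expect_equal(aoil(T1, 2), 0.10 / 0.14)
  expect_equal(additivity(T1, 1), 0.25 / 0.29)
  # locus with no epistatic terms: degenerate AoIL -> 0 with warning
  ls <- fourierLandscape(3, 0, list(1, 2, c(2, 3)), c(0.4, 0.2, 0.3))
  expect_warning(a <- aoil(ls, 1), "no epistatic")
  expect_equal(a, 0)
  expect_equal(additivity(ls, 1), 1)           # purely additive locus
  ls2 <- fourierLandscape(3, 0, list(c(1, 2), 2), c(0.4, 0.1))
  expect_equal(additivity(ls2, 1), 0)          # purely epistatic locus
  expect_warning(a2 <- additivity(ls2, 3), "all-zero")
  expect_true(is.nan(a2))
  # AoIL below one half guarantees a non-positive directed trend
  set.seed(107)
  for (r in 1:20) {
    ls <- randomSparseLandscape(sample(3:7, 1))
    i <- sample.int(nLoci(ls), 1)
    if (suppressWarnings(aoil(ls, i)) < 0.5)
      expect_lte(-2 * directedVF(ls, i), 1e-12)
  }
})

test_that("brute-force regression returns the exact closed-form identities", {
  T1 <- toyMap()
  sym <- bruteForceRegression(T1, 1, "symmetric")
  expect_equal(sym$slope, -2 * 0.29 / 0.38)
  expect_equal(sym$residualVariance, 4 * (0.29 / 0.38) * (0.09 / 0.38) * 0.38)
  dir <- bruteForceRegression(T1, 1, "directed")
  expect_equal(dir$slope, -0.8)
  expect_equal(dir$additiveTerm, 2 * 0.5 * (1 - 0.4))
  expect_error(bruteForceRegression(randomSparseLandscape(5), 1, cap = 4),
               "capped")
  set.seed(108)
  for (r in 1:10) {
    ls <- randomSparseLandscape(8)
    i <- sample.int(8, 1)
    b <- bruteForceRegression(ls, i, "symmetric")
    expect_equal(b$slope, -2 * varianceFraction(ls, i), tolerance = 1e-12)
  }
})

test_that("summed variance fractions exceed one exactly when epistatic", {
  T1 <- toyMap()
  expect_equal(sum(varianceFractions(T1)), 0.42 / 0.38)
  add <- fourierLandscape(6, 0, as.list(1:6), rnorm(6))
  expect_equal(sum(varianceFractions(add)), 1)
  set.seed(109)
  for (r in 1:10) {
    ls <- randomSparseLandscape(sample(3:8, 1))
    expect_gte(sum(varianceFractions(ls)), 1 - 1e-12)
  }
})

test_that("locus summaries collect the per-locus statistics", {
  T1 <- toyMap()
  s <- locusSummary(T1)
  expect_equal(s$additive, c(0.5, -0.3))
  expect_equal(s$vf, varianceFractions(T1))
  expect_true(all(s$aoil >= 0 & s$aoil <= 1))
})

test_that("landscape JSON serialization round-trips bit exactly", {
  set.seed(110)
  ls <- randomSparseLandscape(6, baseline = pi)
  path <- tempfile(fileext = ".json")
  writeLandscape(ls, path)
  back <- readLandscape(path)
  expect_identical(landscapeCoefs(back), landscapeCoefs(ls))
  expect_identical(baseline(back), baseline(ls))
  expect_identical(landscapeTerms(back), landscapeTerms(ls))
})

test_that("malformed genotypes and loci are rejected", {
  T1 <- toyMap()
  expect_error(evaluateFitness(T1, c(1, 1, 1)), "length")
  expect_error(evaluateFitness(T1, c(1, 0)), "alleles")
  expect_error(mutationEffect(T1, c(1, 1), 3), "out of range")
  expect_error(fourierLandscape(2, 0, list(c(1, 1)), 1), "strictly")
  expect_error(fourierLandscape(2, 0, list(3), 1), "out of")
})
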