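test_that("two-point directed fits recover slope and directed VF", {
  # backgrounds y = 0, 1 with mutant fitness 1.4, 1.6: slope -0.8
  p <- mutationPanel(c(0, 1), matrix(c(1.4, 1.6), ncol = 1,
                                     dimnames = list(NULL, "m1")))
  f <- fitMutation(p, "m1")
  expect_equal(f$slope, -0.8)
  expect_equal(f$vTildeHat, 0.4)
  expect_equal(f$intercept, 1.4)
})

test_that("panel estimators equal exact statistics on full subcubes", {
  set.seed(401)
  for (r in 1:10) {
    l <- sample(3:8, 1)
    ls <- randomSparseLandscape(l)
    i <- sample.int(l, 1)
    G <- enumerateGenotypes(l)
    full <- buildPanel(ls, i, G)
    expect_equal(fitMutation(full, 1)$vTildeHat, varianceFraction(ls, i),
                 tolerance = 1e-9)
    expect_equal(estimateVFConcat(full, 1), varianceFraction(ls, i),
                 tolerance = 1e-9)
    sub <- buildPanel(ls, i, G[G[, i] == -1, , drop = FALSE])
    expect_equal(fitMutation(sub, 1)$vTildeHat, directedVF(ls, i),
                 tolerance = 1e-9)
    expect_equal(suppressWarnings(estimateAoil(sub, 1)),
                 suppressWarnings(aoil(ls, i)), tolerance = 1e-9)
    expect_equal(suppressWarnings(estimateAdditivity(sub, 1)),
                 suppressWarnings(additivity(ls, i)), tolerance = 1e-9)
  }
})

test_that("residual construction is identical to the OLS residuals", {
  set.seed(402)
  ls <- randomSparseLandscape(6)
  p <- buildPanel(ls, 2, randomGenotypes(40, 6))
  f <- fitMutation(p, 1)
  y <- backgroundFitness(p)
  s <- mutantFitness(p)[, 1] - y
  ols <- s - (f$intercept + f$slope * y)
  expect_equal(unname(f$residuals), unname(ols), tolerance = 1e-12)
  expect_equal(sum(f$residuals), 0, tolerance = 1e-10)
})

test_that("degenerate panels are flagged rather than fitted", {
  p <- mutationPanel(c(1, 1, 1), matrix(c(1.2, 1.3, 1.1), ncol = 1))
  expect_warning(f <- fitMutation(p, 1), "constant background")
  expect_true(is.na(f$slope))
  # constant effect: zero slope, zero residuals
  p2 <- mutationPanel(c(0, 1, 2), matrix(c(0.5, 1.5, 2.5), ncol = 1))
  f2 <- fitMutation(p2, 1)
  expect_equal(f2$slope, 0)
  expect_equal(unname(f2$residuals), rep(0, 3))
  expect_warning(a <- estimateAoil(p2, 1), "degenerate")
  expect_equal(a, 0)
  expect_equal(estimateAdditivity(p2, 1), 1)
  expect_error(fitMutation(p2, "nope"), "unknown mutation")
  expect_error(fitMutation(mutationPanel(1, matrix(1)), 1), "at least 2")
})

test_that("concatenation estimator hits its null and bound cases", {
  # identical mutant and background fitness: rho = 1, v = 0
  y <- c(0.2, 0.9, 1.4, 2.0)
  expect_equal(estimateVFConcat(
    mutationPanel(y, matrix(y, ncol = 1)), 1), 0)
  # perfectly anti-correlated: v = 1
  expect_equal(estimateVFConcat(
    mutationPanel(y, matrix(2 - y, ncol = 1)), 1), 1, tolerance = 1e-12)
  expect_error(estimateVFConcat(
    mutationPanel(c(1, 1, 1), matrix(c(1, 1, 1), ncol = 1)), 1),
    "zero variance")
})

test_that("additivity estimator matches its moment definition", {
  set.seed(403)
  y <- rnorm(30)
  s <- 0.8 + 0.3 * rnorm(30)
  p <- mutationPanel(y, matrix(y + s, ncol = 1))
  fhat2 <- (mean(s) / 2)^2
  epi <- mean((s - mean(s))^2) / 4
  expect_equal(estimateAdditivity(p, 1), fhat2 / (fhat2 + epi))
  # zero-mean varying effects: purely epistatic, additivity 0
  s0 <- s - mean(s)
  expect_equal(estimateAdditivity(
    mutationPanel(y, matrix(y + s0, ncol = 1)), 1), 0)
  # constant nonzero effect: noiseless additive locus, additivity 1
  expect_equal(estimateAdditivity(
    mutationPanel(y, matrix(y + 0.7, ncol = 1)), 1), 1)
  expect_warning(a <- estimateAdditivity(
    mutationPanel(y, matrix(y, ncol = 1)), 1), "all-zero")
  expect_true(is.nan(a))
})

test_that("panel-wide fits collect every estimator", {
  set.seed(404)
  ls <- randomSparseLandscape(7)
  p <- buildPanel(ls, c(1, 4, 6), randomGenotypes(60, 7))
  fit <- fitPanel(p)
  st <- fitStats(fit)
  expect_equal(nrow(st), 3)
  expect_equal(st$vTildeHat, -st$slope / 2)
  expect_equal(names(fitResiduals(fit)), st$mutation)
  expect_true(all(st$n == 60))
})

test_that("the residual-variance relation recovers proportionality", {
  # at this small scale the relation is positive and clearly linear; the
  # sharp R^2 > 0.8 proportionality at the reference landscape scale is
  # exercised by the acceptance suite
  set.seed(405)
  ls <- suppressWarnings(cnLandscape(100, 300, muBar = 0.05))
  loci <- order(-varianceFractions(ls))[1:15]
  fit <- fitPanel(buildPanel(ls, loci, randomGenotypes(250, 100)))
  rel <- residualVarianceRelation(fit, applyFilter = FALSE)
  expect_gt(rel$slope, 0)
  expect_gt(rel$rSquared, 0.3)
  # additive landscape, directed mutations: residual variances vanish
  add <- fourierLandscape(8, 0, as.list(1:8), rnorm(8))
  G <- randomGenotypes(50, 8)
  fadd <- fitPanel(synthPanel(add, loci = c(1, 3, 5, 7), backgrounds = G,
                              noiseSd = 0))
  expect_true(all(fitStats(fadd)$residualVariance < 1e-20))
  # identical mutations collapse the relation to a single point
  y <- rnorm(10)
  same <- mutationPanel(y, matrix(rep(y + 0.3 * y + 0.1, 3), ncol = 3))
  expect_error(residualVarianceRelation(fitPanel(same), applyFilter = FALSE),
               "at least 3")
  expect_error(residualVarianceRelation(
    fitPanel(buildPanel(add, 1:2, G))), "at least 3")
})

test_that("measurement noise inflates residual variance by about 2 sigma^2", {
  set.seed(406)
  ls <- suppressWarnings(cnLandscape(100, 300, muBar = 0.05))
  loci <- sample.int(100, 12)
  G <- randomGenotypes(200, 100)
  G[, loci] <- -1
  clean <- fitPanel(synthPanel(ls, loci = loci, backgrounds = G, noiseSd = 0))
  set.seed(407)
  noisy <- fitPanel(synthPanel(ls, loci = loci, backgrounds = G,
                               noiseSd = 0.05))
  inflation <- mean(fitStats(noisy)$residualVariance -
                      fitStats(clean)$residualVariance)
  expect_gt(inflation, 0.5 * 2 * 0.05^2)
  expect_lt(inflation, 2.0 * 2 * 0.05^2)
  rel <- residualVarianceRelation(noisy, applyFilter = FALSE)
  expect_gt(rel$slope, 0)
})

test_that("estimation error shrinks as backgrounds accumulate", {
  set.seed(408)
  ls <- suppressWarnings(cnLandscape(100, 300, muBar = 0.05))
  loci <- sample.int(100, 15)
  vex <- varianceFraction(ls, loci)
  rmse <- vapply(c(50, 400), function(nb) {
    vt <- fitStats(fitPanel(buildPanel(ls, loci,
                                       randomGenotypes(nb, 100))))$vTildeHat
    sqrt(mean((vt - vex)^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("pooled residual prediction honours its degenerate contracts", {
  st <- data.frame(mutation = "m1", n = 10, slope = 0, intercept = 0,
                   vTildeHat = 0, vHat = 0, aoilHat = 0, additivityHat = 1,
                   residualVariance = 0, locus = 1L, direction = "flip")
  fit <- new("GlobalEpistasisFit", stats = st,
             residuals = list(m1 = rep(0, 10)), normalization = "population")
  pr <- pooledResidualPrediction(fit, nDraws = 100)
  expect_true(all(pr$predicted == 0))
  expect_null(pr$ks)
  pr0 <- pooledResidualPrediction(fit, nDraws = 0)
  expect_equal(length(pr0$predicted), 0)
})
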