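test_that("the B-spline basis tiles the trial and matches Cox-de Boor", {
  p <- TrialProtocol(nNeurons = 2, nTrials = 3, trialMs = 1000, seed = 1)
  cov <- bsplineBasis(p)
  B <- covariateData(cov)
  binsPerTrial <- 1000 / 5
  expect_equal(nrow(B), 3 * binsPerTrial)
  expect_equal(ncol(B), 1000 / 100 + 3)   # T/d + 3 columns for order 4
  ## partition of unity inside the trial
  expect_equal(rowSums(B), rep(1, nrow(B)), tolerance = 1e-12)
  ## constant weights give constant drive; zero weights give zero
  expect_equal(drop(B %*% rep(-3, ncol(B))), rep(-3, nrow(B)),
               tolerance = 1e-12)
  expect_equal(drop(B %*% rep(0, ncol(B))), rep(0, nrow(B)))
  ## direct recursion oracle
  centers <- (seq_len(binsPerTrial) - 0.5) * 5
  knots <- seq(-300, 1300, by = 100)
  expect_equal(unname(B[seq_len(binsPerTrial), ]),
               coxDeBoor(knots, centers, 4), tolerance = 1e-10)
  ## incompatible knot spacing is refused
  pBad <- TrialProtocol(nNeurons = 2, nTrials = 1, trialMs = 1000,
                        knotSpacingMs = 100, seed = 1)
  pBad@knotSpacingMs <- 300
  expect_error(bsplineBasis(pBad), "knot")
})

test_that("Zernike polynomials follow the Noll table", {
  set.seed(81)
  rho <- runif(30); theta <- runif(30, 0, 2 * pi)
  cov <- zernikeBasis(rho, theta)
  Zb <- covariateData(cov)
  ## piston is constant 1
  expect_equal(Zb[, 1], rep(1, 30))
  ## at rho = 0 all polynomials with nonzero azimuthal order vanish
  z0 <- covariateData(zernikeBasis(0, 0.7))
  expect_equal(unname(z0[1, c(2, 3, 5, 6, 7, 8, 9, 10)]), rep(0, 8))
  ## generic radial-series oracle, indices 1..10
  nollN <- c(0, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  nollM <- c(0, 1, -1, 0, -2, 2, -1, 1, -3, 3)
  for (j in 1:10)
    expect_equal(Zb[, j], zernikeOracle(nollN[j], nollM[j], rho, theta),
                 tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(zernikeBasis(1.2, 0), "rho")
})

test_that("ground-truth models respect the drive band and rate target", {
  p <- TrialProtocol(nNeurons = 8, nTrials = 20, jMax = 0, seed = 82)
  gt <- makeGroundTruth(p)
  H <- modelFields(gt$model, gt$covariates)
  ## fields stay in [-6, -2] shifted by the per-neuron offsets
  for (n in 1:8) {
    expect_gte(min(H[, n]), -6 + gt$offsets[n] - 1e-9)
    expect_lte(max(H[, n]), -2 + gt$offsets[n] + 1e-9)
  }
  ## expected rate within 10% of 5 Hz under independence
  expRate <- colMeans(plogis(H)) / 0.005
  expect_true(all(abs(expRate - 5) / 5 < 0.10))
  ## determinism
  gt2 <- makeGroundTruth(p)
  expect_identical(stimWeights(gt$model), stimWeights(gt2$model))
  expect_identical(couplings(gt$model), couplings(gt2$model))
})

test_that("default protocol yields 500 bins per trial and ~5 Hz rates", {
  p <- TrialProtocol(nNeurons = 10, nTrials = 10, jMax = 0, seed = 83)
  sim <- simulateProtocol(p)
  expect_equal(trialLength(sim$raster), 500L)
  rates <- colMeans(spikeMatrix(sim$raster)) / binWidth(sim$raster)
  expect_lt(abs(mean(rates) - 5) / 5, 0.10)
})

test_that("Gibbs sampling matches independence and correlation structure", {
  ## J = 0: per-neuron frequencies match logistic(h) within 3 binomial SE
  set.seed(84)
  beta <- matrix(c(-3, -2.5, -3.5), 1, 3)
  m0 <- IsingModel(beta, matrix(0, 3, 3))
  cov <- CovariateMatrix(matrix(1, 12000, 1))
  r0 <- gibbsSample(m0, cov, seed = 85)
  pTrue <- plogis(beta[1, ])
  se <- sqrt(pTrue * (1 - pTrue) / 12000)
  expect_true(all(abs(colMeans(spikeMatrix(r0)) - pTrue) < 3 * se))

  ## strong positive coupling induces positive same-bin correlation
  J <- matrix(c(0, 1, 1, 0), 2)
  m2 <- IsingModel(matrix(c(-2, -2), 1, 2), J)
  cov2 <- CovariateMatrix(matrix(1, 8000, 1))
  r2 <- gibbsSample(m2, cov2, seed = 86)
  expect_gt(cor(spikeMatrix(r2))[1, 2], 0)

  ## determinism end-to-end
  rA <- gibbsSample(m2, cov2, seed = 87)
  rB <- gibbsSample(m2, cov2, seed = 87)
  expect_identical(spikeMatrix(rA), spikeMatrix(rB))
})

test_that("Gibbs pattern frequencies converge to the exact law (N = 4)", {
  inst <- randomInstance(N = 4, L = 1, jScale = 0.5, seed = 88, hShift = -1)
  L <- 100000
  cov <- CovariateMatrix(covariateData(inst$covariates)[rep(1, L), ,
                                                        drop = FALSE])
  r <- gibbsSample(inst$model, cov, sweepsPerBin = 5, burnIn = 5, seed = 89)
  tab <- buildPatternTable(r)
  H <- modelFields(inst$model, inst$covariates)
  Z <- partitionValues(exactPartition(inst$model, inst$covariates))[1]
  pEmp <- rep(0, 16)
  pEmp[patternKeys(tab) + 1] <- patternCounts(tab) / L
  pExact <- apply(allPatterns(4), 1, function(pat)
    patternProbability(inst$model, pat, H[1, ], Z))
  tv <- sum(abs(pEmp - pExact)) / 2
  expect_lt(tv, 0.01)
})

test_that("Bernoulli pattern forecasts bracket simulated counts", {
  ## saturated limit: all 8 patterns of 3 fair coins
  fSat <- bernoulliPatternForecast(BernoulliPopulationSpec(3, 0.5, 1e7))
  expect_equal(fSat$nPatterns, 8)
  ## sparse limit: only the silent pattern
  fSparse <- bernoulliPatternForecast(BernoulliPopulationSpec(10, 1e-6, 1000))
  expect_lt(abs(fSparse$nPatterns - 1), 0.05)

  ## order-of-magnitude agreement with simulation (upper-bound character)
  spec <- BernoulliPopulationSpec(10, 0.025, 50000)
  f <- bernoulliPatternForecast(spec)
  set.seed(90)
  counts <- vapply(1:20, function(k) {
    X <- matrix(rbinom(spec@L * spec@N, 1L, spec@p), spec@L, spec@N)
    nrow(patterns(buildPatternTable(SpikeRaster(X))))
  }, numeric(1))
  expect_lt(f$nPatterns, 2 * mean(counts) + 1)
  expect_gt(2 * f$nPatterns, mean(counts))
})

test_that("missing-mass calibration hits its target", {
  p <- TrialProtocol(nNeurons = 10, nTrials = 10, seed = 91)
  cal <- calibrateMissingMass(p, 0.01)
  expect_lt(abs(cal$missingMass - 0.01) / 0.01, 0.2)
  ## the calibrated protocol reproduces the achieved missing mass
  sim <- simulateProtocol(cal$protocol)
  expect_equal(goodTuring(buildPatternTable(sim$raster)), cal$missingMass)
})
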