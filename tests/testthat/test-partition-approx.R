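test_that("observed-pattern sums match full and subset enumeration", {
  inst <- randomInstance(N = 4, L = 6, seed = 61)
  H <- modelFields(inst$model, inst$covariates)
  J <- couplings(inst$model)

  ## full pattern set reproduces the exact partition function
  full <- allPatterns(4)
  rFull <- SpikeRaster(full[rep(seq_len(16), 2), ])
  tabFull <- buildPatternTable(rFull)
  X <- observedSumX(inst$model, tabFull, inst$covariates)
  Z <- exactPartition(inst$model, inst$covariates)
  expect_equal(logPartition(X), logPartition(Z), tolerance = 1e-12)

  ## silent-only table: X = exp(0) = 1 everywhere
  tab0 <- buildPatternTable(SpikeRaster(matrix(0L, 3, 4)))
  X0 <- observedSumX(inst$model, tab0, inst$covariates)
  expect_equal(partitionValues(X0), rep(1, 6))

  ## 5-pattern subset versus naive summation
  set.seed(62)
  sub <- full[sample(16, 5), ]
  tabSub <- buildPatternTable(SpikeRaster(sub))
  Xs <- observedSumX(inst$model, tabSub, inst$covariates)
  naive <- vapply(seq_len(nrow(H)), function(t)
    naiveSubsetSum(patterns(tabSub), H[t, ], J), numeric(1))
  expect_equal(partitionValues(Xs), naive, tolerance = 1e-10)

  ## X never exceeds Z and grows monotonically with the pattern set
  expect_true(all(logPartition(Xs) <= logPartition(Z) + 1e-12))
  tabSub2 <- buildPatternTable(SpikeRaster(rbind(sub, full[1:10, ])))
  Xs2 <- observedSumX(inst$model, tabSub2, inst$covariates)
  expect_true(all(partitionValues(Xs2) >= partitionValues(Xs) - 1e-12))
})

test_that("Good-Turing tracks the analytic missing mass of Bernoulli neurons", {
  set.seed(63)
  N <- 10; p <- 0.025; L <- 20000
  X <- matrix(rbinom(L * N, 1L, p), L, N)
  tab <- buildPatternTable(SpikeRaster(X))
  mGT <- goodTuring(tab)
  ## realized missing mass under the product-Bernoulli law
  pats <- allPatterns(N)
  q <- apply(pats, 1, function(s) prod(ifelse(s == 1, p, 1 - p)))
  keys <- as.numeric(pats %*% 2^(0:(N - 1)))
  observed <- keys %in% patternKeys(tab)
  mTrue <- sum(q[!observed])
  ## Good-Turing concentration: within 3 * sqrt(E[M]/L) of the truth
  expect_lt(abs(mGT - mTrue), 3 * sqrt(mTrue / L) + 3 / L)
})

test_that("chain probabilities factorize, normalize and match enumeration", {
  p <- TrialProtocol(nNeurons = 4, nTrials = 8, trialMs = 1000, jMax = 0.6,
                     seed = 64)
  sim <- simulateProtocol(p)
  fit <- fitConditionalChain(sim$raster, sim$covariates)
  chain <- fit$chain
  C <- covariateData(sim$covariates)

  ## explicit enumeration oracle of the chain joint
  ord <- chainOrdering(chain)
  oracle <- function(pat, cRow) {
    pr <- 1
    for (k in seq_along(ord)) {
      eta <- sum(cRow * stimWeights(chain)[[k]])
      if (k < length(ord)) {
        later <- ord[(k + 1):length(ord)]
        eta <- eta + 2 * sum(pat[later] * neighborWeights(chain)[[k]])
      }
      pk <- plogis(eta)
      pr <- pr * if (pat[ord[k]] == 1) pk else 1 - pk
    }
    pr
  }
  P <- allPatterns(4)
  for (row in c(3, 111)) {
    probs <- apply(P, 1, function(pat) chainPatternProb(chain, pat, C[row, ]))
    expect_equal(probs, apply(P, 1, oracle, cRow = C[row, ]),
                 tolerance = 1e-12)
    expect_equal(sum(probs), 1, tolerance = 1e-10)
  }

  ## zero neighbor weights: product of marginal logistics
  chain0 <- new("ChainModel", ordering = chainOrdering(chain),
                stimWeights = stimWeights(chain),
                neighborWeights = lapply(neighborWeights(chain),
                                         function(w) w * 0))
  pat <- c(1, 0, 1, 0)
  etas <- vapply(seq_along(ord), function(k)
    sum(C[1, ] * stimWeights(chain0)[[k]]), numeric(1))
  marg <- prod(ifelse(pat[ord] == 1, plogis(etas), 1 - plogis(etas)))
  expect_equal(chainPatternProb(chain0, pat, C[1, ]), marg,
               tolerance = 1e-12)
})

test_that("missing mass equals the complement sum over unobserved patterns", {
  p <- TrialProtocol(nNeurons = 4, nTrials = 8, trialMs = 1000, jMax = 0.5,
                     seed = 65)
  sim <- simulateProtocol(p)
  fit <- fitConditionalChain(sim$raster, sim$covariates)
  tab <- buildPatternTable(sim$raster)
  M <- missingMass(fit$chain, tab, sim$covariates)
  C <- covariateData(sim$covariates)
  P <- allPatterns(4)
  keys <- as.numeric(P %*% 2^(0:3))
  unobserved <- P[!(keys %in% patternKeys(tab)), , drop = FALSE]
  for (row in c(2, 120)) {
    direct <- sum(apply(unobserved, 1, function(pat)
      chainPatternProb(fit$chain, pat, C[row, ])))
    expect_equal(missingMassValues(M)[row], direct, tolerance = 1e-10)
  }
  ## full table: missing mass identically zero
  tabFull <- buildPatternTable(SpikeRaster(allPatterns(4)))
  Mfull <- missingMass(fit$chain, tabFull, sim$covariates)
  expect_equal(missingMassValues(Mfull), rep(0, nBins(sim$raster)),
               tolerance = 1e-12)
})

test_that("Z reconstruction from missing mass follows the inversion identity", {
  X <- PartitionSeries(log(c(2, 3, 5)), "X_only")
  ## M = 0 leaves X unchanged
  M0 <- new("MissingMassSeries", values = rep(0, 3),
            method = "good_turing_constant")
  expect_equal(partitionValues(zFromMissingMass(X, M0)), c(2, 3, 5))
  ## M = 0.5, X = 2: Y = 2 so Z = 4
  Mh <- new("MissingMassSeries", values = rep(0.5, 3),
            method = "conditional_logistic")
  expect_equal(partitionValues(zFromMissingMass(X, Mh))[1], 4)
  ## M >= 1 is an error naming the offending bins
  Mbad <- new("MissingMassSeries", values = c(0.2, 1.0, 0.3),
              method = "conditional_logistic")
  expect_error(zFromMissingMass(X, Mbad), "bin")
})

test_that("plugging the true missing mass reproduces the exact partition", {
  ## the inversion Y = X M/(1-M) is exact when M comes from enumeration
  inst <- randomInstance(N = 5, L = 10, seed = 66, hShift = -2)
  H <- modelFields(inst$model, inst$covariates)
  J <- couplings(inst$model)
  set.seed(67)
  obs <- allPatterns(5)[sample(32, 12), ]
  tab <- buildPatternTable(SpikeRaster(obs))
  X <- observedSumX(inst$model, tab, inst$covariates)
  Zex <- exactPartition(inst$model, inst$covariates)
  keys <- as.numeric(allPatterns(5) %*% 2^(0:4))
  unobs <- allPatterns(5)[!(keys %in% patternKeys(tab)), ]
  ## true M(s) by explicit complement enumeration
  Mtrue <- vapply(seq_len(nrow(H)), function(t)
    naiveSubsetSum(unobs, H[t, ], J) /
      (naiveSubsetSum(unobs, H[t, ], J) +
       naiveSubsetSum(patterns(tab), H[t, ], J)), numeric(1))
  M <- new("MissingMassSeries", values = Mtrue,
           method = "conditional_logistic")
  Zrec <- zFromMissingMass(X, M)
  expect_equal(logPartition(Zrec), logPartition(Zex), tolerance = 1e-8)
})

test_that("importance sampling is exact in the zero-variance case", {
  ## J = 0 with the true marginals as proposal: every ratio identical
  beta <- matrix(c(-2, 0.5, -1, 0.3), 2, 2)
  m <- IsingModel(beta, matrix(0, 2, 2))
  cov <- CovariateMatrix(cbind(1, c(0.2, 0.8, 0.5)))
  Zis <- importanceSamplingZ(m, cov, nSamples = 50, seed = 68,
                             proposal = beta)
  H <- covariateData(cov) %*% beta
  expect_equal(partitionValues(Zis), apply(1 + exp(H), 1, prod),
               tolerance = 1e-12)
  expect_equal(mcStandardErrors(Zis), rep(0, 3), tolerance = 1e-12)
  expect_error(importanceSamplingZ(m, cov, nSamples = 1, seed = 1,
                                   proposal = beta), "2")
})

test_that("importance sampling is calibrated and obeys the root-n law", {
  inst <- randomInstance(N = 6, L = 30, seed = 69, hShift = -1.5)
  Zex <- partitionValues(exactPartition(inst$model, inst$covariates))
  prop <- stimWeights(inst$model)  # stimulus-only proposal (J dropped)
  Zis <- importanceSamplingZ(inst$model, inst$covariates, nSamples = 20000,
                             seed = 70, proposal = prop)
  covered <- abs(partitionValues(Zis) - Zex) <= 4 * mcStandardErrors(Zis)
  expect_gte(mean(covered), 0.95)

  ## doubling the sample count halves the standard error (within noise)
  se1 <- mean(mcStandardErrors(
    importanceSamplingZ(inst$model, inst$covariates, 4000, seed = 71,
                        proposal = prop)))
  se2 <- mean(mcStandardErrors(
    importanceSamplingZ(inst$model, inst$covariates, 16000, seed = 72,
                        proposal = prop)))
  expect_equal(se1 / se2, 2, tolerance = 0.25)
})

test_that("deterministic approximations are exact at J = 0 and ranked at weak coupling", {
  set.seed(73)
  beta <- matrix(rnorm(12, -1.5, 0.5), 2, 6)
  m0 <- IsingModel(beta, matrix(0, 6, 6))
  cov <- CovariateMatrix(cbind(1, runif(8)))
  H <- covariateData(cov) %*% beta
  indep <- apply(1 + exp(H), 1, prod)
  for (meth in c("nmf", "tap", "bethe", "low_rate"))
    expect_equal(partitionValues(deterministicZ(m0, cov, meth)), indep,
                 tolerance = 1e-9)

  ## weak coupling, N = 8: Bethe beats naive mean field almost everywhere,
  ## and the mean-field bound holds bin-wise
  inst <- randomInstance(N = 8, L = 40, jScale = 0.1, seed = 74)
  lZex <- logPartition(exactPartition(inst$model, inst$covariates))
  lNmf <- logPartition(deterministicZ(inst$model, inst$covariates, "nmf"))
  lBet <- logPartition(deterministicZ(inst$model, inst$covariates, "bethe"))
  expect_gte(mean(abs(lBet - lZex) < abs(lNmf - lZex)), 0.8)
  expect_true(all(lNmf <= lZex + 1e-10))
})
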