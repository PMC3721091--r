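## Independent oracles and fixture builders used across the suite.
## Everything here is deliberately naive (enumeration, double loops) so the
## package's vectorized/compiled paths are checked against simple code.

## all 2^N patterns as a (2^N x N) 0/1 matrix
allPatterns <- function(N) {
  as.matrix(expand.grid(rep(list(0:1), N)))[, , drop = FALSE]
}

## naive log weight: explicit double loop over the quadratic form
naiveLogWeight <- function(pattern, h, J) {
  s <- sum(h * pattern)
  N <- length(pattern)
  for (i in seq_len(N)) for (j in seq_len(N))
    s <- s + pattern[i] * J[i, j] * pattern[j]
  s
}

## naive per-bin partition sum in linear space (no log-sum-exp)
naiveZ <- function(h, J) {
  P <- allPatterns(length(h))
  sum(exp(as.numeric(P %*% h) + rowSums((P %*% J) * P)))
}

## naive sum over an explicit pattern subset
naiveSubsetSum <- function(P, h, J) {
  sum(exp(as.numeric(P %*% h) + rowSums((P %*% J) * P)))
}

## random stimulus-driven model + smooth covariates
randomInstance <- function(N, R = 3, L = 20, jScale = 0.4, hShift = -1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- matrix(0, N, N)
  if (N > 1) {
    J[upper.tri(J)] <- runif(N * (N - 1) / 2, -jScale, jScale)
    J <- J + t(J)
  }
  beta <- matrix(rnorm(R * N, hShift, 0.7), R, N)
  cov <- CovariateMatrix(cbind(1, matrix(runif(L * (R - 1)), L, R - 1)))
  list(model = IsingModel(beta, J), covariates = cov)
}

## random binary raster with heterogeneous rates
randomRaster <- function(L, N, pMin = 0.05, pMax = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(N, pMin, pMax)
  SpikeRaster(vapply(p, function(pi) rbinom(L, 1L, pi), integer(L)))
}

## Cox-de Boor recursion, order k, evaluated pointwise
coxDeBoor <- function(knots, x, k) {
  nb <- length(knots) - k
  B <- matrix(0, length(x), length(knots) - 1)
  for (i in seq_len(ncol(B)))
    B[, i] <- as.numeric(x >= knots[i] & x < knots[i + 1])
  for (ord in 2:k) {
    Bn <- matrix(0, length(x), length(knots) - ord)
    for (i in seq_len(ncol(Bn))) {
      d1 <- knots[i + ord - 1] - knots[i]
      d2 <- knots[i + ord] - knots[i + 1]
      t1 <- if (d1 > 0) (x - knots[i]) / d1 * B[, i] else 0
      t2 <- if (d2 > 0) (knots[i + ord] - x) / d2 * B[, i + 1] else 0
      Bn[, i] <- t1 + t2
    }
    B <- Bn
  }
  B[, seq_len(nb), drop = FALSE]
}

## generic Zernike evaluation from the radial-polynomial series
zernikeOracle <- function(n, m, rho, theta) {
  rad <- 0
  for (k in 0:((n - abs(m)) / 2))
    rad <- rad + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + abs(m)) / 2 - k) *
       factorial((n - abs(m)) / 2 - k)) * rho^(n - 2 * k)
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m == 0) 1 else if (m > 0) cos(m * theta) else sin(-m * theta)
  norm * rad * ang
}

## shared cache for the heavier staged experiments used by the acceptance
## tests (built lazily, reused across test blocks)
.acceptanceCache <- new.env(parent = emptyenv())

stagedExperiment <- function(targetMM, seed = 5L) {
  key <- paste0("mm", targetMM, "_", seed)
  if (!is.null(.acceptanceCache[[key]])) return(.acceptanceCache[[key]])
  proto <- TrialProtocol(nNeurons = 20, nTrials = 40, seed = seed)
  cal <- calibrateMissingMass(proto, targetMM)
  sim <- simulateProtocol(cal$protocol)
  tab <- buildPatternTable(sim$raster)
  fp <- fitPseudolikelihood(sim$raster, sim$covariates)
  fc <- fitConditionalChain(sim$raster, sim$covariates)
  Zex <- exactPartition(fp$model, sim$covariates)
  X <- observedSumX(fp$model, tab, sim$covariates)
  Mcl <- missingMass(fc$chain, tab, sim$covariates)
  out <- list(sim = sim, table = tab, model = fp$model, chain = fc$chain,
              Zexact = Zex, X = X, Mcl = Mcl,
              Zcl = zFromMissingMass(X, Mcl),
              Zgt = zFromMissingMass(X, goodTuringSeries(tab, nBins(X))),
              mmGT = goodTuring(tab))
  .acceptanceCache[[key]] <- out
  out
}
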