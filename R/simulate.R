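#' Order-4 B-spline basis tiling the trial
#'
#' Evaluates an order-4 (cubic) B-spline basis on evenly spaced knots
#' covering the trial, at every bin center, and tiles the result across
#' trials. With knot spacing d over a trial of length T the basis has
#' T/d + 3 columns and forms a partition of unity inside the trial, so
#' constant spline weights produce a constant drive.
#'
#' @param protocol a \linkS4class{TrialProtocol}.
#' @return A \linkS4class{CovariateMatrix} with basisKind
#'   "bspline_trial_time" and L = nTrials * trialMs/binMs rows.
#' @export
bsplineBasis <- function(protocol) {
  Tms <- protocol@trialMs; d <- protocol@knotSpacingMs
  if (Tms %% d != 0)
    stop("knot spacing must divide the trial length", call. = FALSE)
  binsPerTrial <- Tms / protocol@binMs
  centers <- (seq_len(binsPerTrial) - 0.5) * protocol@binMs
  knots <- seq(-3 * d, Tms + 3 * d, by = d)
  B <- splines::splineDesign(knots, centers, ord = 4)
  Bfull <- B[rep(seq_len(binsPerTrial), protocol@nTrials), , drop = FALSE]
  CovariateMatrix(Bfull, basisKind = "bspline_trial_time",
                  columnLabels = paste0("bs", seq_len(ncol(B))))
}

## Zernike radial polynomial R_n^m(rho) (m >= 0)
.zernikeRadial <- function(n, m, rho) {
  out <- numeric(length(rho))
  for (k in 0:((n - m) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) *
       factorial((n - m) / 2 - k)) * rho^(n - 2 * k)
  }
  out
}

## Noll index table for j = 1..10: (n, m) with sign of m giving sin/cos
.nollTable <- data.frame(
  j = 1:10,
  n = c(0, 1, 1, 2, 2, 2, 3, 3, 3, 3),
  m = c(0, 1, -1, 0, -2, 2, -1, 1, -3, 3))

#' First ten Zernike polynomials on the unit disc
#'
#' Evaluates Zernike polynomials Z_1..Z_10 (Noll ordering and
#' normalization: piston, tip, tilt, defocus, obliquity/vertical
#' astigmatism, comas, trefoils) at positions (rho, theta) on the unit
#' disc. Used to parameterize spatial (place-field-like) stimulus drive.
#'
#' @param rho radial coordinates in [0, 1].
#' @param theta angular coordinates in radians.
#' @return A \linkS4class{CovariateMatrix} with basisKind "zernike_disc"
#'   and 10 columns.
#' @export
zernikeBasis <- function(rho, theta) {
  stopIfNot(length(rho) == length(theta),
            "rho and theta lengths differ")
  if (any(rho < 0 | rho > 1))
    stop("rho must lie in [0, 1]", call. = FALSE)
  out <- matrix(0, length(rho), 10)
  for (r in seq_len(10)) {
    n <- .nollTable$n[r]; m <- .nollTable$m[r]
    rad <- .zernikeRadial(n, abs(m), rho)
    norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
    ang <- if (m == 0) 1 else if (m > 0) cos(m * theta)
           else sin(abs(m) * theta)
    out[, r] <- norm * rad * ang
  }
  CovariateMatrix(out, basisKind = "zernike_disc",
                  columnLabels = paste0("Z", 1:10))
}

#' Generate a ground-truth stimulus-driven Ising model
#'
#' Draws a model matching the trial protocol: per-neuron spline weights
#' uniform on [-6, -2] (so h_n(t) stays in that band by the partition of
#' unity), then a per-neuron constant offset found by root search so that
#' the J = 0 mean firing rate hits the target within 10%; couplings uniform
#' on [-jMax, jMax], symmetrized, zero diagonal.
#'
#' @param protocol a \linkS4class{TrialProtocol}; its seed makes the draw
#'   reproducible.
#' @return List with \code{model} (\linkS4class{IsingModel}),
#'   \code{covariates} (\linkS4class{CovariateMatrix}) and \code{offsets}
#'   (the per-neuron rate-matching shifts).
#' @export
makeGroundTruth <- function(protocol) {
  cov <- bsplineBasis(protocol)
  Ctrial <- covariateData(cov)[seq_len(protocol@trialMs / protocol@binMs), ,
                               drop = FALSE]
  M <- ncol(Ctrial); N <- protocol@nNeurons
  targetP <- protocol@targetRateHz * protocol@binMs / 1000
  stopIfNot(targetP > 0 && targetP < 1, "unattainable rate target")
  withSeed(protocol@seed, {
    beta <- matrix(runif(M * N, -6, -2), M, N)
    h0 <- Ctrial %*% beta
    offsets <- vapply(seq_len(N), function(n) {
      f <- function(d) mean(logistic(h0[, n] + d)) - targetP
      if (f(-10) > 0 || f(15) < 0)
        stop("unattainable rate target", call. = FALSE)
      uniroot(f, c(-10, 15), tol = 1e-10)$root
    }, numeric(1))
    ## partition of unity: adding a constant to every weight shifts h by it
    beta <- beta + matrix(offsets, M, N, byrow = TRUE)
    J <- matrix(0, N, N)
    if (N > 1) {
      up <- runif(N * (N - 1) / 2, -protocol@jMax, protocol@jMax)
      J[upper.tri(J)] <- up
      J <- J + t(J)
    }
    list(model = new("IsingModel", beta = beta, J = J),
         covariates = cov, offsets = offsets)
  })
}

#' Gibbs-sample a raster from a stimulus-driven Ising model
#'
#' Single-site Gibbs sampling using the exact logistic full conditionals.
#' Each bin runs \code{burnIn + sweepsPerBin} full sweeps warm-started from
#' the previous bin's state (the first bin starts from independent draws at
#' logistic(h)); the final state is recorded. Consecutive bins share similar
#' fields under trial protocols, so warm starts mix quickly.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param covariates \linkS4class{CovariateMatrix}.
#' @param sweepsPerBin sampling sweeps per bin (default 10).
#' @param burnIn burn-in sweeps per bin (default 20).
#' @param seed RNG seed (NULL uses the current stream).
#' @param binWidth seconds per bin for the returned raster (default 5 ms).
#' @param trialLength optional bins per trial recorded on the raster.
#' @return A \linkS4class{SpikeRaster}.
#' @export
gibbsSample <- function(model, covariates, sweepsPerBin = 10L, burnIn = 20L,
                        seed = NULL, binWidth = 0.005, trialLength = NA) {
  stopIfNot(sweepsPerBin >= 1, "sweeps_per_bin must be >= 1")
  H <- modelFields(model, covariates)
  X <- withSeed(seed,
    gibbs_sample_cpp(H, couplings(model), as.integer(burnIn),
                     as.integer(sweepsPerBin)))
  SpikeRaster(X, binWidth = binWidth, trialLength = trialLength)
}

#' Simulate a full trial-protocol experiment
#'
#' Ground-truth model plus Gibbs-sampled raster for a
#' \linkS4class{TrialProtocol}, with bin width and trial structure recorded
#' on the raster.
#'
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param sweepsPerBin,burnIn Gibbs settings (defaults 10 and 20).
#' @return List with \code{model}, \code{covariates}, \code{raster}.
#' @export
simulateProtocol <- function(protocol, sweepsPerBin = 10L, burnIn = 20L) {
  gt <- makeGroundTruth(protocol)
  raster <- gibbsSample(gt$model, gt$covariates, sweepsPerBin, burnIn,
                        seed = subSeed(protocol@seed, 7L),
                        binWidth = protocol@binMs / 1000,
                        trialLength = protocol@trialMs / protocol@binMs)
  list(model = gt$model, covariates = gt$covariates, raster = raster)
}

#' Forecast pattern counts for a Bernoulli population
#'
#' Rule-of-thumb forecast for N neurons firing independently with per-bin
#' probability p over L bins: the expected unique-pattern count is
#' sum_K min\{choose(N,K), Binom(K; N,p) * L\} (the binomial branch is an
#' approximate upper bound that treats every K-spike observation as new),
#' and the Good-Turing missing-mass forecast sums the binomial term over
#' the K where that branch is active, divided by L.
#'
#' @param spec a \linkS4class{BernoulliPopulationSpec}.
#' @return List with \code{nPatterns} and \code{missingMass}.
#' @export
bernoulliPatternForecast <- function(spec) {
  validObject(spec)
  K <- 0:spec@N
  hard <- choose(spec@N, K)
  obs <- dbinom(K, spec@N, spec@p) * spec@L
  active <- obs < hard
  list(nPatterns = sum(pmin(hard, obs)),
       missingMass = sum(obs[active]) / spec@L)
}

#' Calibrate a protocol to a target Good-Turing missing mass
#'
#' Stages experiments at a prescribed Good-Turing missing mass (e.g. 1, 2 or
#' 7%) without hand-picked parameters. The missing mass is not monotone in
#' the coupling half-range alone - very strong couplings drive the network
#' into a saturated high-rate attractor where the pattern repertoire
#' collapses - so the search moves along a single excitability path x:
#' jMax = min(x, jCap), and beyond the cap the target firing rate is scaled
#' by (1 + (x - jCap)). The cap (default 0.5) keeps every coupling draw in
#' the stimulus-driven regime, where realized rates track the intended
#' target; large missing masses are then reached through elevated rates,
#' mirroring how they arise in real recordings. Along this path the
#' simulated missing mass grows monotonically, and bisection on an
#' expanding bracket finds the target within \code{relTol} relative error.
#' Spline weights are redrawn under the protocol seed at every candidate,
#' so the result is reproducible.
#'
#' @param protocol a \linkS4class{TrialProtocol}; its jMax slot is ignored,
#'   its targetRateHz is the baseline rate.
#' @param target desired Good-Turing missing mass (0 < target < 1).
#' @param relTol relative tolerance (default 0.2).
#' @param maxIter bisection cap (default 12).
#' @param jCap largest coupling half-range used (default 1).
#' @return List with \code{protocol} (jMax and targetRateHz set to the
#'   calibrated values), \code{missingMass} achieved, and the path
#'   coordinate \code{x}.
#' @export
calibrateMissingMass <- function(protocol, target, relTol = 0.2,
                                 maxIter = 12L, jCap = 0.5) {
  protoAt <- function(x) {
    p <- protocol
    p@jMax <- min(x, jCap)
    p@targetRateHz <- protocol@targetRateHz * (1 + max(0, x - jCap))
    p
  }
  mmAt <- function(x) {
    sim <- simulateProtocol(protoAt(x))
    goodTuring(buildPatternTable(sim$raster))
  }
  lo <- 0; hi <- 1.5
  mLo <- mmAt(lo)
  if (mLo > target * (1 + relTol))
    stop("target missing mass below the uncoupled baseline (",
         format(mLo, digits = 3), ")", call. = FALSE)
  if (abs(mLo - target) <= relTol * target)
    return(list(protocol = protoAt(lo), missingMass = mLo, x = lo))
  mHi <- mmAt(hi)
  tries <- 0L
  while (mHi < target && tries < 4L) {
    hi <- hi * 1.5; mHi <- mmAt(hi); tries <- tries + 1L
  }
  if (mHi < target)
    stop("cannot reach target missing mass ", target,
         " within the calibration path", call. = FALSE)
  best <- list(x = hi, mm = mHi)
  for (it in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    mMid <- mmAt(mid)
    if (abs(mMid - target) < abs(best$mm - target))
      best <- list(x = mid, mm = mMid)
    if (abs(mMid - target) <= relTol * target) break
    if (mMid < target) lo <- mid else hi <- mid
  }
  if (abs(best$mm - target) > relTol * target)
    stop("calibration failed: best missing mass ",
         format(best$mm, digits = 3), " for target ", target, call. = FALSE)
  list(protocol = protoAt(best$x), missingMass = best$mm, x = best$x)
}
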