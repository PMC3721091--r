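#' Observed-pattern partition sum X(s)
#'
#' The exactly computed part of Z(s): the sum of exp(h(s).sigma +
#' sigma' J sigma) over the unique patterns in the table. The quadratic
#' energies are precomputed once per pattern and the field term is one
#' matrix product against the unique covariate rows, so the cost is
#' O(U * N * Npat) for U unique stimulus rows.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param table a \linkS4class{PatternTable} (training data).
#' @param covariates \linkS4class{CovariateMatrix} for the bins to evaluate.
#' @return A \linkS4class{PartitionSeries} with method "X_only".
#' @export
observedSumX <- function(model, table, covariates) {
  P <- patterns(table)
  stopIfNot(nrow(P) >= 1, "empty pattern table")
  stopIfNot(ncol(P) == nNeurons(model),
            "pattern dimension does not match model")
  H <- modelFields(model, covariates)
  uu <- uniqueRowIndex(H)
  quad <- patternQuad(P, couplings(model))
  E <- quad + P %*% t(uu$rows)            # Npat x U
  logXu <- colLogSumExp(E)
  PartitionSeries(logXu[uu$index], "X_only",
                  opCount = nrow(uu$rows) * nrow(P) * ncol(P))
}

## log chain probability of each table pattern (rows) at each unique
## covariate row (cols): Npat x U matrix, computed position by position in
## log space.
chainLogProbMatrix <- function(chain, P, Cu) {
  N <- nNeurons(chain)
  ord <- chainOrdering(chain)
  Npat <- nrow(P); U <- nrow(Cu)
  logp <- matrix(0, Npat, U)
  for (k in seq_len(N)) {
    sStim <- drop(Cu %*% chain@stimWeights[[k]])     # length U
    nb <- if (k < N) {
      later <- ord[(k + 1):N]
      drop(2 * (P[, later, drop = FALSE] %*% chain@neighborWeights[[k]]))
    } else numeric(Npat)
    eta <- outer(nb, sStim, "+")                     # Npat x U
    sig <- P[, ord[k]]
    logp <- logp + sig * eta - log1pexp(eta)
  }
  logp
}

#' Chain probability of one pattern
#'
#' The normalized joint probability assigned by the conditional-logistic
#' chain: the product over chain positions of the logistic conditionals
#' evaluated at the pattern's bits, computed in log space.
#'
#' @param chain a \linkS4class{ChainModel}.
#' @param pattern length-N 0/1 vector (original neuron order).
#' @param covariateRow length-R stimulus covariate vector.
#' @return Probability in (0, 1).
#' @export
chainPatternProb <- function(chain, pattern, covariateRow) {
  stopIfNot(length(pattern) == nNeurons(chain),
            "pattern length does not match chain")
  P <- matrix(as.numeric(pattern), nrow = 1)
  Cu <- matrix(as.numeric(covariateRow), nrow = 1)
  exp(chainLogProbMatrix(chain, P, Cu)[1, 1])
}

#' Stimulus-modulated missing mass from the chain
#'
#' M(s) = 1 - sum over the table's patterns of the chain's joint probability,
#' per bin (evaluated once per unique covariate row and broadcast). Tiny
#' negative values from rounding are clipped to zero and counted; values
#' >= 1 are left in place here and refused by
#' \code{\link{zFromMissingMass}}.
#'
#' @param chain a \linkS4class{ChainModel}.
#' @param table a \linkS4class{PatternTable} (training data).
#' @param covariates \linkS4class{CovariateMatrix} for the bins to evaluate.
#' @return A \linkS4class{MissingMassSeries} with method
#'   "conditional_logistic".
#' @export
missingMass <- function(chain, table, covariates) {
  P <- patterns(table)
  stopIfNot(nrow(P) >= 1, "empty pattern table")
  stopIfNot(ncol(P) == nNeurons(chain),
            "table and chain dimensions disagree")
  C <- covariateData(covariates)
  uu <- uniqueRowIndex(C)
  logp <- chainLogProbMatrix(chain, P, uu$rows)
  Mu <- 1 - colSums(exp(logp))
  neg <- Mu < 0
  if (any(neg)) Mu[neg] <- 0
  M <- Mu[uu$index]
  new("MissingMassSeries", values = M, method = "conditional_logistic",
      nClipped = as.integer(sum(neg[uu$index])),
      opCount = nrow(uu$rows) * nrow(P) * nNeurons(chain))
}

#' Constant Good-Turing missing-mass series
#'
#' Broadcasts the Good-Turing estimate M_GT = singletons / L to every bin,
#' the assumption being that observed and unobserved patterns covary with
#' the stimulus identically.
#'
#' @param table training \linkS4class{PatternTable}.
#' @param nBinsOut number of bins in the evaluation series (defaults to the
#'   table's own length).
#' @return A \linkS4class{MissingMassSeries} with method
#'   "good_turing_constant".
#' @export
goodTuringSeries <- function(table, nBinsOut = nBins(table)) {
  new("MissingMassSeries",
      values = rep(goodTuring(table), nBinsOut),
      method = "good_turing_constant", nClipped = 0L)
}

#' Partition function from observed sum and missing mass
#'
#' Inverts the missing-mass relation: Y(s) = X(s) M(s)/(1 - M(s)), so
#' Z(s) = X(s) + Y(s) = X(s)/(1 - M(s)), computed in log space. Any bin with
#' M >= 1 signals a broken missing-mass fit and raises an error naming the
#' bins rather than clipping.
#'
#' @param X a \linkS4class{PartitionSeries} (typically method "X_only").
#' @param M a \linkS4class{MissingMassSeries} of the same length.
#' @return A \linkS4class{PartitionSeries} with method "good_turing" or
#'   "conditional_logistic" according to the missing-mass method.
#' @export
zFromMissingMass <- function(X, M) {
  m <- missingMassValues(M)
  stopIfNot(length(m) == nBins(X), "series lengths differ")
  bad <- which(m >= 1)
  if (length(bad))
    stop("missing mass >= 1 in bin(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "",
         "; the missing-mass fit is broken", call. = FALSE)
  method <- if (seriesMethod(M) == "good_turing_constant") "good_turing"
            else "conditional_logistic"
  mOps <- if (is.na(M@opCount)) 0 else M@opCount
  PartitionSeries(logPartition(X) - log1p(-m), method,
                  opCount = operationCount(X) + mOps)
}

#' Importance-sampling estimate of Z(s)
#'
#' Monte Carlo estimate per unique stimulus row: draw n patterns from the
#' independent-Bernoulli proposal q(sigma|s) defined by stimulus-only
#' logistic fits, and average the ratios w(sigma)/q(sigma|s) of the
#' unnormalized Ising weight to the proposal probability (log-sum-exp
#' stabilized). Fresh samples are drawn for each unique row and results are
#' broadcast to the bins sharing it; mc_se is the per-unique-row standard
#' error of the ratio mean.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param covariates \linkS4class{CovariateMatrix}.
#' @param nSamples samples per unique stimulus row (>= 2).
#' @param seed RNG seed (NULL uses the current RNG stream).
#' @param proposal R x N weight matrix from
#'   \code{\link{fitIndependentProposal}}.
#' @return A \linkS4class{PartitionSeries} with method
#'   "importance_sampling" and per-bin \code{mcStandardErrors}.
#' @export
importanceSamplingZ <- function(model, covariates, nSamples, seed = NULL,
                                proposal) {
  stopIfNot(nSamples >= 2, "need at least 2 samples")
  C <- covariateData(covariates)
  stopIfNot(nrow(proposal) == ncol(C), "proposal rows must match covariates")
  uu <- uniqueRowIndex(C)
  H <- uu$rows %*% stimWeights(model)     # U x N target fields
  Q <- uu$rows %*% proposal               # U x N proposal fields
  J <- couplings(model)
  U <- nrow(H); N <- ncol(H)
  logZ <- numeric(U); se <- numeric(U)
  withSeed(seed, {
    for (u in seq_len(U)) {
      q <- logistic(Q[u, ])
      S <- matrix(rbinom(nSamples * N, 1L, rep(q, each = nSamples)),
                  nSamples, N)
      logw <- drop(S %*% H[u, ]) + patternQuad(S, J)
      logq <- drop(S %*% log(q) + (1 - S) %*% log1p(-q))
      lr <- logw - logq
      m <- max(lr)
      r <- exp(lr - m)
      logZ[u] <- m + log(mean(r))
      se[u] <- exp(m) * sd(r) / sqrt(nSamples)
    }
  })
  PartitionSeries(logZ[uu$index], "importance_sampling",
                  mcSE = se[uu$index], opCount = U * nSamples * N)
}

## ---- deterministic baselines ------------------------------------------

## entropy of independent Bernoulli magnetizations
.bernEntropy <- function(m) {
  m <- pmin(pmax(m, 1e-15), 1 - 1e-15)
  -sum(m * log(m) + (1 - m) * log1p(-m))
}

## naive mean-field / TAP fixed points by damped iteration from
## m = logistic(h); returns list(m, converged)
.mfFixedPoint <- function(h, J, tap, maxIter, tol, damping) {
  m <- logistic(h)
  J2 <- J * J
  ok <- FALSE
  for (it in seq_len(maxIter)) {
    arg <- h + 2 * drop(J %*% m)
    if (tap) {
      chi <- m * (1 - m)
      arg <- arg - 2 * (2 * m - 1) * drop(J2 %*% chi)
    }
    mNew <- (1 - damping) * m + damping * logistic(arg)
    if (max(abs(mNew - m)) < tol) { m <- mNew; ok <- TRUE; break }
    m <- mNew
  }
  list(m = m, converged = ok)
}

.logZnmf <- function(h, J, m) {
  sum(h * m) + .bernEntropy(m) + drop(m %*% J %*% m)
}

## loopy BP on the fully connected pairwise graph; messages as log odds
.bethe <- function(h, J, maxIter, tol, damping) {
  N <- length(h)
  M <- matrix(0, N, N)       # M[i,j] = log-odds message i -> j
  Jp <- 2 * J                # pairwise coefficient in the standard coding
  ok <- FALSE
  for (it in seq_len(maxIter)) {
    inSum <- h + colSums(M)              # h_i + sum_k M[k,i]
    ## cavity field a[i,j] = h_i + sum_{k != j} M[k,i] = inSum[i] - M[j,i]
    A <- matrix(inSum, N, N) - t(M)      # rows i, cols j
    Mnew <- log1pexp(A + Jp) - log1pexp(A)
    diag(Mnew) <- 0
    if (max(abs(Mnew - M)) < tol) { M <- Mnew; ok <- TRUE; break }
    M <- (1 - damping) * M + damping * Mnew
  }
  inSum <- h + colSums(M)
  bi <- logistic(inSum)                  # singleton beliefs
  ## Bethe free energy from beliefs
  logZ <- 0
  H1 <- -(bi * log(pmax(bi, 1e-300)) +
          (1 - bi) * log(pmax(1 - bi, 1e-300)))
  A <- matrix(inSum, N, N) - t(M)        # cavity fields a[i,j]
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ai <- A[i, j]; aj <- A[j, i]
    lw <- c(0, aj, ai, ai + aj + Jp[i, j])   # (0,0),(0,1),(1,0),(1,1)
    lz <- logSumExp(lw)
    b <- exp(lw - lz)
    Hij <- -sum(b * log(pmax(b, 1e-300)))
    ## edge energy: pairwise coupling only (fields are counted once below)
    logZ <- logZ + b[4] * Jp[i, j] + Hij
  }
  logZ <- logZ + sum(bi * h) - (N - 2) * sum(H1)
  list(logZ = logZ, converged = ok)
}

## independent-pair (low-firing-rate) expansion
.logZlowRate <- function(h, J) {
  m <- logistic(h)
  lz <- sum(log1pexp(h))
  N <- length(h)
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    lz <- lz + log1p(m[i] * m[j] * expm1(2 * J[i, j]))
  lz
}

#' Deterministic partition-function approximations
#'
#' Four standard deterministic estimates of Z(s), evaluated per unique
#' stimulus row and broadcast:
#' \describe{
#'   \item{nmf}{naive mean field: damped fixed point of
#'     m_i = logistic(h_i + 2 (J m)_i) started at logistic(h); log Z is the
#'     variational lower bound h.m + H(m) + m' J m.}
#'   \item{tap}{TAP-corrected mean field: the fixed point includes the
#'     Onsager reaction term and log Z adds chi' (J o J) chi with
#'     chi = m(1-m).}
#'   \item{bethe}{Bethe free energy of the loopy-belief-propagation fixed
#'     point on the fully connected pairwise graph (parallel schedule,
#'     damped messages).}
#'   \item{low_rate}{independent-pair low-firing-rate expansion
#'     log Z = sum_i log(1+e^h_i) + sum_(i<j) log(1 + m_i m_j (e^(2J_ij)-1))
#'     with m = logistic(h).}
#' }
#' All four are exact when J = 0. Non-convergence of a fixed point is
#' flagged per bin via a warning; values are still returned.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param covariates \linkS4class{CovariateMatrix}.
#' @param method one of "nmf", "tap", "bethe", "low_rate".
#' @param maxIter iteration cap for fixed points (default 500).
#' @param tol fixed-point tolerance (default 1e-8).
#' @param damping damping factor in (0, 1] (default 0.5).
#' @return A \linkS4class{PartitionSeries} with the chosen method.
#' @export
deterministicZ <- function(model, covariates,
                           method = c("nmf", "tap", "bethe", "low_rate"),
                           maxIter = 500L, tol = 1e-8, damping = 0.5) {
  method <- match.arg(method)
  H <- modelFields(model, covariates)
  J <- couplings(model)
  uu <- uniqueRowIndex(H)
  U <- nrow(uu$rows)
  logZ <- numeric(U)
  nFail <- 0L
  for (u in seq_len(U)) {
    h <- uu$rows[u, ]
    if (method == "low_rate") {
      logZ[u] <- .logZlowRate(h, J)
    } else if (method == "bethe") {
      r <- .bethe(h, J, maxIter, tol, damping)
      logZ[u] <- r$logZ
      if (!r$converged) nFail <- nFail + 1L
    } else {
      r <- .mfFixedPoint(h, J, tap = method == "tap", maxIter, tol, damping)
      logZ[u] <- .logZnmf(h, J, r$m)
      if (method == "tap") {
        chi <- r$m * (1 - r$m)
        logZ[u] <- logZ[u] + drop(chi %*% (J * J) %*% chi)
      }
      if (!r$converged) nFail <- nFail + 1L
    }
  }
  if (nFail > 0)
    warning(method, " fixed point unconverged for ", nFail,
            " unique stimulus row(s); values returned anyway")
  PartitionSeries(logZ[uu$index], method,
                  opCount = U * nNeurons(model)^2)
}
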