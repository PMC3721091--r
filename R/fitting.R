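#' Ridge-penalized logistic regression by IRLS
#'
#' Maximizes the Bernoulli log-likelihood with logit link minus
#' (ridge/2) * ||w||^2 by Newton (iteratively reweighted least squares) steps
#' with step halving. Convergence is declared when the per-observation
#' gradient max|X'(y - p) - ridge * w| / n drops below \code{tol}. The fit is
#' fully deterministic given its inputs. No intercept is added: the design is
#' used as supplied (stimulus bases such as B-splines span a constant
#' themselves).
#'
#' @param design n x p design matrix.
#' @param response length-n 0/1 vector.
#' @param ridge nonnegative ridge penalty (default 1e-4).
#' @param tol convergence tolerance on the scaled gradient (default 1e-8).
#' @param maxIter Newton iteration cap (default 100).
#' @return List with \code{weights} (length p) and \code{report}
#'   (\linkS4class{FitReport}); non-convergence is flagged and warned about,
#'   weights are still returned.
#' @examples
#' x <- matrix(1, 100, 1)
#' y <- rep(c(1, 0), c(25, 75))
#' fitLogistic(x, y, ridge = 1e-10)$weights  # ~ qlogis(0.25)
#' @export
fitLogistic <- function(design, response, ridge = 1e-4, tol = 1e-8,
                        maxIter = 100L) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  n <- nrow(X)
  stopIfNot(length(y) == n, "design rows must match response length")
  stopIfNot(all(is.finite(X)) && all(y %in% c(0, 1)),
            "design must be finite and response binary")
  stopIfNot(ridge >= 0, "ridge must be nonnegative")
  p <- ncol(X)
  w <- numeric(p)
  eta <- drop(X %*% w)
  mu <- logistic(eta)
  negll <- function(eta, w)
    sum(log1pexp(eta)) - sum(y * eta) + ridge / 2 * sum(w^2)
  f <- negll(eta, w)
  usedRidge <- ridge
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    g <- drop(crossprod(X, y - mu)) - usedRidge * w
    if (max(abs(g)) / n <= tol) { converged <- TRUE; break }
    wt <- mu * (1 - mu)
    Hm <- crossprod(X * wt, X)
    diag(Hm) <- diag(Hm) + usedRidge
    step <- tryCatch(solve(Hm, g), error = function(e) NULL)
    if (is.null(step)) {
      ## rank-deficient normal equations: ridge rescue
      usedRidge <- max(usedRidge * 100, 1e-6)
      warning("rank-deficient design; ridge increased to ", usedRidge)
      diag(Hm) <- diag(Hm) + usedRidge
      step <- solve(Hm, g)
    }
    lam <- 1
    repeat {
      wNew <- w + lam * step
      etaNew <- drop(X %*% wNew)
      fNew <- negll(etaNew, wNew)
      if (fNew <= f + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    if (max(abs(wNew - w)) < 1e-12) {
      w <- wNew; eta <- etaNew; mu <- logistic(eta); f <- fNew
      g <- drop(crossprod(X, y - mu)) - usedRidge * w
      converged <- max(abs(g)) / n <= tol * 10
      break
    }
    w <- wNew; eta <- etaNew; mu <- logistic(eta); f <- fNew
  }
  if (!converged)
    warning("logistic fit did not reach tolerance after ", iter,
            " iterations; returning current weights")
  dev <- 2 * (sum(log1pexp(eta)) - sum(y * eta))
  rep <- new("FitReport", converged = converged, iterations = iter,
             deviance = dev, ridge = usedRidge)
  list(weights = w, report = rep)
}

#' Order neurons by descending mean firing rate
#'
#' The chain factorization conditions high-rate neurons on low-rate ones:
#' position 1 gets the highest-rate neuron, position N the lowest. Ties are
#' broken by ascending original index.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @return Integer permutation of 1..N.
#' @export
orderNeuronsByRate <- function(raster) {
  rates <- colMeans(spikeMatrix(raster))
  order(-rates, seq_along(rates))
}

## shared design-block construction: [C(s), 2 * sigma_j ...]
.checkFittable <- function(X) {
  m <- colMeans(X)
  bad <- which(m == 0 | m == 1)
  if (length(bad))
    stop("neuron(s) ", paste(bad, collapse = ", "),
         " never spike or always spike; their conditional regressions are ",
         "degenerate", call. = FALSE)
}

#' Fit a stimulus-driven Ising model by pseudo-likelihood
#'
#' Each neuron's full conditional is exactly logistic, so each sigma_i is
#' regressed on [C(s), \{2 sigma_j\}_\{j != i\}]; with the factor-2 coding the
#' neighbor coefficients estimate J_ji directly. The two per-pair estimates
#' are symmetrized by averaging, the diagonal is zero, and the stimulus block
#' gives beta.
#'
#' @param raster training \linkS4class{SpikeRaster}.
#' @param covariates matching \linkS4class{CovariateMatrix}.
#' @param ridge ridge penalty for every regression (default 1e-4).
#' @param tol,maxIter passed to \code{\link{fitLogistic}}.
#' @return List with \code{model} (\linkS4class{IsingModel}) and
#'   \code{report} (\linkS4class{FitReport}, one entry per neuron).
#' @export
fitPseudolikelihood <- function(raster, covariates, ridge = 1e-4,
                                tol = 1e-8, maxIter = 100L) {
  X <- spikeMatrix(raster)
  C <- covariateData(covariates)
  stopIfNot(nrow(X) == nrow(C), "raster and covariates bin counts differ")
  .checkFittable(X)
  N <- ncol(X); R <- ncol(C)
  full <- cbind(C, 2 * X)
  beta <- matrix(0, R, N)
  J <- matrix(0, N, N)
  conv <- logical(N); iters <- integer(N); devs <- numeric(N)
  ridges <- numeric(N)
  for (i in seq_len(N)) {
    cols <- c(seq_len(R), R + setdiff(seq_len(N), i))
    fit <- fitLogistic(full[, cols, drop = FALSE], X[, i], ridge = ridge,
                       tol = tol, maxIter = maxIter)
    beta[, i] <- fit$weights[seq_len(R)]
    J[setdiff(seq_len(N), i), i] <- fit$weights[-seq_len(R)]
    conv[i] <- fit$report@converged
    iters[i] <- fit$report@iterations
    devs[i] <- fit$report@deviance
    ridges[i] <- fit$report@ridge
  }
  J <- (J + t(J)) / 2
  diag(J) <- 0
  list(model = new("IsingModel", beta = beta, J = J),
       report = new("FitReport", converged = conv, iterations = iters,
                    deviance = devs, ridge = ridges))
}

#' Fit the rate-ordered conditional-logistic chain
#'
#' After ordering neurons by descending mean rate, position k's regression
#' predicts that neuron's spikes from [C(s), \{2 sigma_j : j at positions
#' > k\}]; position N (lowest rate) is stimulus-only. The resulting chain
#' defines a normalized joint distribution whose parameters need not (and in
#' general do not) match the Ising model's.
#'
#' @inheritParams fitPseudolikelihood
#' @return List with \code{chain} (\linkS4class{ChainModel}) and
#'   \code{report} (\linkS4class{FitReport}).
#' @export
fitConditionalChain <- function(raster, covariates, ridge = 1e-4,
                                tol = 1e-8, maxIter = 100L) {
  X <- spikeMatrix(raster)
  C <- covariateData(covariates)
  stopIfNot(nrow(X) == nrow(C), "raster and covariates bin counts differ")
  .checkFittable(X)
  N <- ncol(X); R <- ncol(C)
  ord <- orderNeuronsByRate(raster)
  stim <- vector("list", N)
  neigh <- vector("list", N)
  conv <- logical(N); iters <- integer(N); devs <- numeric(N)
  ridges <- numeric(N)
  for (k in seq_len(N)) {
    later <- if (k < N) ord[(k + 1):N] else integer(0)
    design <- cbind(C, 2 * X[, later, drop = FALSE])
    fit <- fitLogistic(design, X[, ord[k]], ridge = ridge, tol = tol,
                       maxIter = maxIter)
    stim[[k]] <- fit$weights[seq_len(R)]
    nw <- fit$weights[-seq_len(R)]
    names(nw) <- as.character(later)
    neigh[[k]] <- nw
    conv[k] <- fit$report@converged
    iters[k] <- fit$report@iterations
    devs[k] <- fit$report@deviance
    ridges[k] <- fit$report@ridge
  }
  list(chain = new("ChainModel", ordering = as.integer(ord),
                   stimWeights = stim, neighborWeights = neigh),
       report = new("FitReport", converged = conv, iterations = iters,
                    deviance = devs, ridge = ridges))
}

#' Fit the independent-neuron (stimulus-only) logistic model
#'
#' One logistic regression of each neuron on C(s) alone. Used as the
#' importance-sampling proposal distribution.
#'
#' @inheritParams fitPseudolikelihood
#' @return R x N weight matrix.
#' @export
fitIndependentProposal <- function(raster, covariates, ridge = 1e-4,
                                   tol = 1e-8, maxIter = 100L) {
  X <- spikeMatrix(raster)
  C <- covariateData(covariates)
  .checkFittable(X)
  vapply(seq_len(ncol(X)), function(i)
    fitLogistic(C, X[, i], ridge = ridge, tol = tol,
                maxIter = maxIter)$weights,
    numeric(ncol(C)))
}
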