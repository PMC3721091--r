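#' Ratio distribution between two partition series
#'
#' Summarizes the bin-wise ratio Z_num(s)/Z_den(s) (computed as
#' exp(logZ_num - logZ_den)): the mean, the 0.005/0.05/0.95/0.995 quantiles
#' (linear interpolation of order statistics, quantile type 7) and the
#' maximum absolute deviation of the 99% bounds from 1. The ratio of any
#' pattern's probability under the two normalizations equals the inverse
#' partition ratio, so this is also the distribution of probability
#' mis-normalization.
#'
#' @param num,den \linkS4class{PartitionSeries} of equal length.
#' @return A \linkS4class{RatioSummary}.
#' @export
ratioDistribution <- function(num, den) {
  stopIfNot(nBins(num) == nBins(den), "series lengths differ")
  r <- exp(logPartition(num) - logPartition(den))
  q <- quantile(r, c(0.005, 0.05, 0.95, 0.995), type = 7, names = FALSE)
  names(q) <- c("q0.005", "q0.05", "q0.95", "q0.995")
  new("RatioSummary", mean = mean(r), quantiles = q,
      maxAbsDeviation = max(abs(q[c(1, 4)] - 1)), n = length(r))
}

ratioSummaryToList <- function(x) {
  list(mean = x@mean, q0.005 = x@quantiles[["q0.005"]],
       q0.05 = x@quantiles[["q0.05"]], q0.95 = x@quantiles[["q0.95"]],
       q0.995 = x@quantiles[["q0.995"]],
       max_abs_deviation = x@maxAbsDeviation, n = x@n)
}

## split trial-structured bins into train/test by whole trials
splitTrials <- function(L, trialLength, trainFraction) {
  if (trainFraction >= 1) return(list(train = seq_len(L), test = seq_len(L)))
  nTrials <- L / trialLength
  nTrain <- max(1L, floor(nTrials * trainFraction))
  train <- seq_len(nTrain * trialLength)
  test <- setdiff(seq_len(L), train)
  if (!length(test)) test <- train
  list(train = train, test = test)
}

subsetRaster <- function(raster, idx) {
  SpikeRaster(spikeMatrix(raster)[idx, , drop = FALSE],
              binWidth = binWidth(raster))
}

subsetCovariates <- function(cov, idx) {
  CovariateMatrix(covariateData(cov)[idx, , drop = FALSE],
                  basisKind = basisKind(cov))
}

#' Run a full simulation-and-evaluation experiment
#'
#' Orchestrates the validation workflow: simulate the trial protocol
#' (optionally calibrating couplings to a target Good-Turing missing mass),
#' split into training and test trials, fit the Ising model by
#' pseudo-likelihood and the conditional-logistic chain on the training
#' split, compute every requested partition series on the evaluation split
#' (training tables and fits throughout), and summarize each against the
#' reference: exact enumeration when N is within the cap, otherwise the
#' conditional-logistic series. Per-method operation counts are recorded so
#' the linear-in-L-and-Npat versus exponential-in-N scaling can be checked
#' without wall-clock timing.
#'
#' @param config list with elements \code{protocol}
#'   (\linkS4class{TrialProtocol}), \code{methods} (character subset of
#'   "exact", "x_only", "gt", "cl", "is", "nmf", "tap", "bethe",
#'   "low_rate"), and optionally \code{trainFraction} (default 0.75),
#'   \code{evalOn} ("test" default, or "train"), \code{nSamples} for
#'   importance sampling (default 5000), \code{targetMissingMass} for
#'   calibration, \code{exactCap} (default 24).
#' @return List (JSON-serializable) with the achieved missing masses, the
#'   per-method \linkS4class{RatioSummary} blocks, operation counts and the
#'   reference method used.
#' @export
runExperiment <- function(config) {
  stopIfNot(is(config$protocol, "TrialProtocol"), "config$protocol missing")
  methods <- config$methods
  known <- c("exact", "x_only", "gt", "cl", "is", "nmf", "tap", "bethe",
             "low_rate")
  stopIfNot(all(methods %in% known), "unknown method requested")
  cap <- config$exactCap %||% 24L
  proto <- config$protocol
  N <- proto@nNeurons
  if ("exact" %in% methods && N > cap)
    stop("stage simulate/config: exact enumeration requested for N = ", N,
         " above cap ", cap, call. = FALSE)
  if (!is.null(config$targetMissingMass)) {
    cal <- calibrateMissingMass(proto, config$targetMissingMass)
    proto <- cal$protocol
  }
  sim <- simulateProtocol(proto)
  trainFraction <- config$trainFraction %||% 0.75
  sp <- splitTrials(nBins(sim$raster), trialLength(sim$raster),
                    trainFraction)
  evalIdx <- if ((config$evalOn %||% "test") == "train") sp$train
             else sp$test
  trainRaster <- subsetRaster(sim$raster, sp$train)
  trainCov <- subsetCovariates(sim$covariates, sp$train)
  evalCov <- subsetCovariates(sim$covariates, evalIdx)

  fitPL <- fitPseudolikelihood(trainRaster, trainCov)
  fitCL <- fitConditionalChain(trainRaster, trainCov)
  table <- buildPatternTable(trainRaster)
  model <- fitPL$model

  X <- observedSumX(model, table, evalCov)
  mCL <- missingMass(fitCL$chain, table, evalCov)
  series <- list()
  for (m in methods) {
    series[[m]] <- switch(m,
      exact = exactPartition(model, evalCov, cap = cap),
      x_only = X,
      gt = zFromMissingMass(X, goodTuringSeries(table, nBins(X))),
      cl = zFromMissingMass(X, mCL),
      is = importanceSamplingZ(model, evalCov,
             nSamples = config$nSamples %||% 5000L,
             seed = subSeed(proto@seed, 11L),
             proposal = fitIndependentProposal(trainRaster, trainCov)),
      nmf = deterministicZ(model, evalCov, "nmf"),
      tap = deterministicZ(model, evalCov, "tap"),
      bethe = deterministicZ(model, evalCov, "bethe"),
      low_rate = deterministicZ(model, evalCov, "low_rate"))
  }
  reference <- if ("exact" %in% methods) "exact" else "cl"
  if (!reference %in% names(series))
    stop("stage evaluate: no reference series (request 'exact' or 'cl')",
         call. = FALSE)
  ref <- series[[reference]]
  ratios <- lapply(series, function(s) {
    rs <- ratioDistribution(s, ref)
    ratioSummaryToList(rs)
  })
  list(
    protocol = list(neurons = N, trials = proto@nTrials,
                    trial_ms = proto@trialMs, bin_ms = proto@binMs,
                    j_max = proto@jMax, seed = proto@seed),
    split = list(train_bins = length(sp$train),
                 eval_bins = length(evalIdx),
                 eval_on = config$evalOn %||% "test"),
    missing_mass = list(good_turing = goodTuring(table),
                        conditional_logistic_mean =
                          mean(missingMassValues(mCL))),
    n_patterns = nrow(patterns(table)),
    reference = reference,
    ratios = ratios,
    op_counts = lapply(series, operationCount),
    converged = list(pseudolikelihood = all(fitPL$report@converged),
                     chain = all(fitCL$report@converged)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
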