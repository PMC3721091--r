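#' SpikeRaster: binned binary population spike trains
#'
#' An L x N matrix of 0/1 spike indicators, one row per time bin and one
#' column per neuron, together with the bin width in seconds and, for
#' trial-structured recordings, the number of bins per trial.
#'
#' @slot data integer matrix of 0/1, L bins x N neurons.
#' @slot binWidth bin width in seconds.
#' @slot trialLength bins per trial (NA if the recording is not
#'   trial-structured); when set, L must be a multiple of it.
#' @export
setClass("SpikeRaster",
  representation(data = "matrix", binWidth = "numeric",
                 trialLength = "integer"),
  prototype(binWidth = 0.005, trialLength = NA_integer_))

setValidity("SpikeRaster", function(object) {
  d <- object@data
  if (nrow(d) < 1L || ncol(d) < 1L) return("raster must be at least 1 x 1")
  if (!all(d %in% c(0L, 1L))) return("raster entries must be 0 or 1")
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0) return("binWidth must be a positive scalar")
  tl <- object@trialLength
  if (!is.na(tl) && (tl < 1L || nrow(d) %% tl != 0L))
    return("L must be a multiple of trialLength")
  TRUE
})

#' Construct a SpikeRaster
#'
#' @param data L x N matrix with entries in \{0, 1\}.
#' @param binWidth bin width in seconds (default 5 ms).
#' @param trialLength optional bins per trial.
#' @return A \linkS4class{SpikeRaster}.
#' @examples
#' SpikeRaster(matrix(rbinom(40, 1, 0.2), 10, 4))
#' @export
SpikeRaster <- function(data, binWidth = 0.005, trialLength = NA) {
  storage.mode(data) <- "integer"
  dimnames(data) <- NULL
  new("SpikeRaster", data = data, binWidth = binWidth,
      trialLength = as.integer(trialLength))
}

#' CovariateMatrix: per-bin stimulus design C(s)
#'
#' An L x R real matrix of stimulus covariates aligned row-for-row with a
#' \linkS4class{SpikeRaster}; columns are basis functions (B-splines in trial
#' time, Zernike polynomials on the unit disc, or any user-supplied basis).
#'
#' @slot data L x R numeric matrix; column names label the basis functions.
#' @slot basisKind one of "bspline_trial_time", "zernike_disc", "custom".
#' @export
setClass("CovariateMatrix",
  representation(data = "matrix", basisKind = "character"),
  prototype(basisKind = "custom"))

setValidity("CovariateMatrix", function(object) {
  if (!all(is.finite(object@data))) return("covariates must be finite")
  if (ncol(object@data) < 1L) return("need at least one covariate column")
  if (!object@basisKind %in% c("bspline_trial_time", "zernike_disc", "custom"))
    return("unknown basisKind")
  TRUE
})

#' Construct a CovariateMatrix
#'
#' @param data L x R numeric matrix.
#' @param basisKind basis label; see \linkS4class{CovariateMatrix}.
#' @param columnLabels optional column names.
#' @return A \linkS4class{CovariateMatrix}.
#' @export
CovariateMatrix <- function(data, basisKind = "custom", columnLabels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.null(columnLabels)) colnames(data) <- columnLabels
  if (is.null(colnames(data)))
    colnames(data) <- paste0("c", seq_len(ncol(data)))
  new("CovariateMatrix", data = data, basisKind = basisKind)
}

#' IsingModel: stimulus-driven pairwise maximum-entropy model
#'
#' Parameters of P(sigma | s) = exp(h(s).sigma + sigma' J sigma) / Z(s) with
#' sigma in \{0,1\}^N and h(s) = C(s) beta. J is symmetric with zero
#' diagonal; the factor-2 pairwise convention (sigma' J sigma =
#' 2 sum_\{i<j\} J_ij sigma_i sigma_j) is used throughout.
#'
#' @slot beta R x N stimulus weight matrix.
#' @slot J N x N symmetric coupling matrix, zero diagonal.
#' @export
setClass("IsingModel", representation(beta = "matrix", J = "matrix"))

setValidity("IsingModel", function(object) {
  J <- object@J
  if (nrow(J) != ncol(J)) return("J must be square")
  if (ncol(object@beta) != nrow(J)) return("ncol(beta) must equal nrow(J)")
  if (!isTRUE(all.equal(J, t(J), tolerance = 0, check.attributes = FALSE)))
    return("J must be exactly symmetric")
  if (any(diag(J) != 0)) return("diag(J) must be zero")
  if (!all(is.finite(object@beta)) || !all(is.finite(J)))
    return("parameters must be finite")
  TRUE
})

#' Construct an IsingModel
#'
#' Only the \{0,1\} spin coding is supported; inputs in the \{-1,+1\}
#' convention are refused rather than silently converted. Any nonzero
#' diagonal of J is absorbed into beta (a self-coupling J_ii adds
#' J_ii * sigma_i to the energy, i.e. a constant field on neuron i), with a
#' warning; this requires the covariate basis to span a constant, which is
#' checked loosely.
#'
#' @param beta R x N stimulus weight matrix.
#' @param J N x N coupling matrix; symmetrized as (J + t(J))/2 only when the
#'   asymmetry is at rounding level, otherwise an error.
#' @param spinCoding must be "01".
#' @return An \linkS4class{IsingModel}.
#' @export
IsingModel <- function(beta, J, spinCoding = c("01", "pm1")) {
  spinCoding <- match.arg(spinCoding)
  if (spinCoding != "01")
    stop("only the {0,1} spin coding is supported; convert your model ",
         "explicitly before constructing an IsingModel", call. = FALSE)
  beta <- as.matrix(beta); J <- as.matrix(J)
  storage.mode(beta) <- "double"; storage.mode(J) <- "double"
  if (max(abs(J - t(J))) > 1e-8 * max(1, max(abs(J))))
    stop("J is not symmetric", call. = FALSE)
  J <- (J + t(J)) / 2
  if (any(diag(J) != 0)) {
    warning("nonzero diag(J) absorbed into beta as a constant field")
    dJ <- diag(J)
    ## distribute the constant field over the basis columns assuming they
    ## span a constant (true for B-spline partitions of unity)
    beta <- beta + outer(rep(1 / nrow(beta), nrow(beta)), dJ)
    diag(J) <- 0
  }
  new("IsingModel", beta = beta, J = J)
}

#' PatternTable: unique spike patterns observed in a raster
#'
#' Unique N-bit patterns with occurrence counts, the singleton count driving
#' the Good-Turing estimator, and a per-bin pointer into the pattern list.
#' Canonical pattern key: little-endian bit packing (neuron 1 = least
#' significant bit), exact as a double for N <= 52; patterns are stored in
#' ascending key order so serialized tables are portable.
#'
#' @slot patterns Npat x N 0/1 matrix of unique patterns.
#' @slot keys numeric packed keys (N <= 52) or character keys otherwise.
#' @slot counts occurrences of each pattern; sums to L.
#' @slot binIndex length-L pointer from raster rows into patterns.
#' @export
setClass("PatternTable",
  representation(patterns = "matrix", keys = "ANY", counts = "integer",
                 binIndex = "integer"))

setValidity("PatternTable", function(object) {
  if (nrow(object@patterns) != length(object@counts))
    return("counts length must match pattern count")
  if (sum(object@counts) != length(object@binIndex))
    return("sum(counts) must equal number of bins")
  if (any(object@binIndex < 1L | object@binIndex > nrow(object@patterns)))
    return("binIndex out of range")
  TRUE
})

#' PartitionSeries: per-bin partition-function values
#'
#' Per-bin values of Z(s) for one estimation method, stored in log space.
#' Monte Carlo methods additionally carry per-bin standard errors (on the
#' linear scale).
#'
#' @slot logValues length-L log Z(s).
#' @slot method one of "exact", "X_only", "good_turing",
#'   "conditional_logistic", "importance_sampling", "nmf", "tap", "bethe",
#'   "low_rate".
#' @slot mcSE per-bin Monte Carlo standard errors (length 0 when not
#'   applicable).
#' @slot opCount number of inner-loop terms evaluated while computing the
#'   series (complexity instrumentation).
#' @export
setClass("PartitionSeries",
  representation(logValues = "numeric", method = "character",
                 mcSE = "numeric", opCount = "numeric"),
  prototype(mcSE = numeric(0), opCount = NA_real_))

.partitionMethods <- c("exact", "X_only", "good_turing",
                       "conditional_logistic", "importance_sampling",
                       "nmf", "tap", "bethe", "low_rate")

setValidity("PartitionSeries", function(object) {
  if (!object@method %in% .partitionMethods) return("unknown method")
  if (any(!is.finite(object@logValues))) return("log values must be finite")
  if (length(object@mcSE) &&
      length(object@mcSE) != length(object@logValues))
    return("mcSE length must match values")
  TRUE
})

PartitionSeries <- function(logValues, method, mcSE = numeric(0),
                            opCount = NA_real_) {
  new("PartitionSeries", logValues = as.numeric(logValues), method = method,
      mcSE = as.numeric(mcSE), opCount = as.numeric(opCount))
}

#' MissingMassSeries: per-bin missing mass M(s)
#'
#' The total model probability, per stimulus bin, of all patterns not in the
#' training-data pattern table. Values lie in [0, 1); a value >= 1 signals a
#' broken chain fit and is refused at construction of Z, not clipped.
#'
#' @slot values length-L missing mass in [0, 1).
#' @slot method "good_turing_constant" or "conditional_logistic".
#' @slot nClipped number of bins whose tiny negative rounding error was
#'   clipped to zero.
#' @slot opCount number of inner-loop terms evaluated (complexity
#'   instrumentation).
#' @export
setClass("MissingMassSeries",
  representation(values = "numeric", method = "character",
                 nClipped = "integer", opCount = "numeric"),
  prototype(nClipped = 0L, opCount = NA_real_))

setValidity("MissingMassSeries", function(object) {
  if (!object@method %in% c("good_turing_constant", "conditional_logistic"))
    return("unknown missing-mass method")
  if (any(object@values < 0)) return("missing mass must be >= 0")
  TRUE
})

#' ChainModel: conditional-logistic chain ordered by firing rate
#'
#' The normalized chain factorization P(sigma|s) = prod_k P(sigma_(k) |
#' sigma_(k+1..N); s), one logistic regression per chain position, neurons
#' ordered by descending mean firing rate. Position k conditions only on
#' neurons later in the ordering; position N (lowest rate) is stimulus-only.
#' Neighbor covariates enter the linear predictor as 2 * sigma_j * K.
#'
#' @slot ordering permutation of 1..N, descending mean rate.
#' @slot stimWeights list of N numeric vectors (length R each).
#' @slot neighborWeights list of N numeric vectors; element k has one weight
#'   per neuron at positions k+1..N (named by original neuron index), so
#'   element N has length zero.
#' @export
setClass("ChainModel",
  representation(ordering = "integer", stimWeights = "list",
                 neighborWeights = "list"))

setValidity("ChainModel", function(object) {
  N <- length(object@ordering)
  if (!setequal(object@ordering, seq_len(N)))
    return("ordering must be a permutation of 1..N")
  if (length(object@stimWeights) != N || length(object@neighborWeights) != N)
    return("need one weight set per chain position")
  for (k in seq_len(N))
    if (length(object@neighborWeights[[k]]) != N - k)
      return("position k must have N-k neighbor weights")
  TRUE
})

#' FitReport: convergence bookkeeping for the logistic regressions
#'
#' @slot converged per-regression convergence flags.
#' @slot iterations IRLS iteration counts.
#' @slot deviance final (unpenalized) deviances.
#' @slot ridge ridge penalty actually used per regression.
#' @export
setClass("FitReport",
  representation(converged = "logical", iterations = "integer",
                 deviance = "numeric", ridge = "numeric"))

#' TrialProtocol: simulation protocol for trial-structured drive
#'
#' Describes the repeated-trial stimulus protocol used by the synthetic
#' generator: trials of \code{trialMs} ms discretized at \code{binMs} ms,
#' per-neuron drive built from an order-4 B-spline basis with knots every
#' \code{knotSpacingMs} ms, mean rate near \code{targetRateHz}, and symmetric
#' couplings uniform on [-jMax, jMax].
#'
#' @slot trialMs trial duration, ms (default 2500).
#' @slot binMs bin width, ms (default 5).
#' @slot nTrials number of trials.
#' @slot knotSpacingMs B-spline knot spacing, ms (default 100).
#' @slot targetRateHz target mean firing rate, Hz (default 5).
#' @slot jMax coupling half-range.
#' @slot nNeurons population size.
#' @slot seed RNG seed for the generator.
#' @export
setClass("TrialProtocol",
  representation(trialMs = "numeric", binMs = "numeric", nTrials = "integer",
                 knotSpacingMs = "numeric", targetRateHz = "numeric",
                 jMax = "numeric", nNeurons = "integer", seed = "integer"))

setValidity("TrialProtocol", function(object) {
  if (object@trialMs %% object@binMs != 0)
    return("trialMs must be divisible by binMs")
  if (object@trialMs %% object@knotSpacingMs != 0)
    return("knot spacing must divide the trial length")
  if (object@nTrials < 1L || object@nNeurons < 1L)
    return("need at least one trial and one neuron")
  TRUE
})

#' Construct a TrialProtocol
#'
#' @param nNeurons population size.
#' @param nTrials number of trials.
#' @param trialMs,binMs,knotSpacingMs,targetRateHz,jMax,seed see
#'   \linkS4class{TrialProtocol}.
#' @return A \linkS4class{TrialProtocol}.
#' @examples
#' TrialProtocol(nNeurons = 20, nTrials = 40, jMax = 0.25, seed = 1)
#' @export
TrialProtocol <- function(nNeurons, nTrials, trialMs = 2500, binMs = 5,
                          knotSpacingMs = 100, targetRateHz = 5, jMax = 0.25,
                          seed = 1L) {
  new("TrialProtocol", trialMs = trialMs, binMs = binMs,
      nTrials = as.integer(nTrials), knotSpacingMs = knotSpacingMs,
      targetRateHz = targetRateHz, jMax = jMax,
      nNeurons = as.integer(nNeurons), seed = as.integer(seed))
}

#' BernoulliPopulationSpec: homogeneous Bernoulli population
#'
#' @slot N neurons.
#' @slot p per-bin spike probability, 0 < p < 1.
#' @slot L number of bins.
#' @export
setClass("BernoulliPopulationSpec",
  representation(N = "integer", p = "numeric", L = "numeric"))

setValidity("BernoulliPopulationSpec", function(object) {
  if (object@p <= 0 || object@p >= 1) return("need 0 < p < 1")
  if (object@N < 1L || object@L < 1) return("need N >= 1, L >= 1")
  TRUE
})

#' @rdname BernoulliPopulationSpec-class
#' @param N,p,L see slots.
#' @export
BernoulliPopulationSpec <- function(N, p, L) {
  new("BernoulliPopulationSpec", N = as.integer(N), p = p, L = as.numeric(L))
}

#' RatioSummary: summary of a partition-function ratio distribution
#'
#' Error is quantified by the distribution over bins of Z_estimate(s) /
#' Z_reference(s): its mean, the 0.005/0.05/0.95/0.995 quantiles (linear
#' interpolation of order statistics, type 7), and the maximum absolute
#' deviation of the 99% bounds from 1.
#'
#' @slot mean mean ratio.
#' @slot quantiles named numeric: q0.005, q0.05, q0.95, q0.995.
#' @slot maxAbsDeviation max(|q0.005 - 1|, |q0.995 - 1|).
#' @slot n number of bins summarized.
#' @export
setClass("RatioSummary",
  representation(mean = "numeric", quantiles = "numeric",
                 maxAbsDeviation = "numeric", n = "integer"))
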