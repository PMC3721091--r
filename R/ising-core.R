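#' Per-bin fields h(s) = C(s) beta
#'
#' @param model an \linkS4class{IsingModel}.
#' @param covariates a \linkS4class{CovariateMatrix} (or plain matrix).
#' @return L x N matrix of per-bin, per-neuron fields.
#' @export
modelFields <- function(model, covariates) {
  C <- if (is(covariates, "CovariateMatrix")) covariateData(covariates)
       else as.matrix(covariates)
  stopIfNot(ncol(C) == nrow(model@beta),
            "covariate columns do not match nrow(beta)")
  C %*% model@beta
}

#' Unnormalized log weight of a spike pattern
#'
#' The log of the Ising numerator, h . sigma + sigma' J sigma, with sigma in
#' \{0,1\}. For symmetric J with zero diagonal the quadratic term equals
#' 2 * sum_\{i<j\} sigma_i sigma_j J_ij; the all-zero pattern always has log
#' weight 0.
#'
#' @param pattern length-N 0/1 vector.
#' @param hRow length-N field vector for one bin.
#' @param J N x N symmetric coupling matrix, zero diagonal.
#' @return Scalar log weight.
#' @examples
#' logWeight(c(1, 1), c(0.2, -0.3), matrix(c(0, 0.5, 0.5, 0), 2))
#' @export
logWeight <- function(pattern, hRow, J) {
  pattern <- as.numeric(pattern)
  N <- length(pattern)
  stopIfNot(length(hRow) == N && nrow(J) == N && ncol(J) == N,
            "pattern, fields and J dimensions disagree")
  sum(hRow * pattern) + drop(pattern %*% J %*% pattern)
}

## quadratic energies sigma' J sigma for a matrix of patterns (rows)
patternQuad <- function(P, J) rowSums((P %*% J) * P)

#' Exact stimulus-driven partition function by enumeration
#'
#' Computes Z(s) = sum over all 2^N patterns of exp(h(s).sigma +
#' sigma' J sigma) for every bin, by Gray-code enumeration in log space with
#' max-subtraction. The quadratic energies are computed once per pattern and
#' reused across bins, and only unique covariate rows are evaluated (results
#' are broadcast), so trial-structured protocols cost at most bins-per-trial
#' enumerations. Populations above \code{cap} neurons are refused; use one of
#' the approximations instead.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param covariates a \linkS4class{CovariateMatrix}.
#' @param cap refusal threshold on N (default 24).
#' @return A \linkS4class{PartitionSeries} with method "exact".
#' @examples
#' m <- IsingModel(beta = matrix(0, 1, 3), J = matrix(0, 3, 3))
#' s <- exactPartition(m, CovariateMatrix(matrix(1, 5, 1)))
#' partitionValues(s)  # 2^3 = 8 in every bin
#' @export
exactPartition <- function(model, covariates, cap = 24L) {
  N <- nNeurons(model)
  if (N > cap)
    stop("exact enumeration over 2^", N, " patterns refused (cap ", cap,
         "); use the conditional-logistic or importance-sampling ",
         "approximation", call. = FALSE)
  H <- modelFields(model, covariates)
  uu <- uniqueRowIndex(H)
  logZu <- exact_logz_cpp(uu$rows, model@J)
  PartitionSeries(logZu[uu$index], "exact",
                  opCount = nrow(uu$rows) * 2^N)
}

#' Probability of one pattern under the model
#'
#' exp(logWeight - log Z); Z must be positive (typically from
#' \code{\link{exactPartition}}).
#'
#' @param model an \linkS4class{IsingModel}.
#' @param pattern length-N 0/1 vector.
#' @param hRow length-N field vector for the bin.
#' @param Z partition-function value for the bin.
#' @return Probability in (0, 1].
#' @export
patternProbability <- function(model, pattern, hRow, Z) {
  stopIfNot(is.finite(Z) && Z > 0, "Z must be positive")
  exp(logWeight(pattern, hRow, couplings(model)) - log(Z))
}

#' Tabulate unique patterns in a raster
#'
#' Builds the \linkS4class{PatternTable}: unique patterns, occurrence counts,
#' singleton count and the per-bin pattern index. Patterns are keyed by
#' little-endian bit packing (neuron 1 = least significant bit), exact in a
#' double for N <= 52 and a packed character key above, and ordered by
#' ascending key.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @return A \linkS4class{PatternTable}.
#' @examples
#' r <- SpikeRaster(rbind(c(0, 0), c(0, 1), c(0, 1), c(1, 1)))
#' t <- buildPatternTable(r)
#' patternCounts(t); nSingletons(t)
#' @export
buildPatternTable <- function(raster) {
  X <- spikeMatrix(raster)
  N <- ncol(X)
  if (N <= 52) {
    keys <- drop(X %*% 2^(seq_len(N) - 1))
  } else {
    ## pack 52 neurons per double, join as character
    blocks <- split(seq_len(N), (seq_len(N) - 1) %/% 52)
    parts <- vapply(blocks, function(ix)
      format(drop(X[, ix, drop = FALSE] %*% 2^(seq_along(ix) - 1)),
             trim = TRUE, scientific = FALSE), character(nrow(X)))
    keys <- apply(as.matrix(parts), 1L, paste, collapse = "|")
  }
  first <- !duplicated(keys)
  ukeys <- keys[first]
  ord <- order(ukeys)
  ukeys <- ukeys[ord]
  pat <- X[first, , drop = FALSE][ord, , drop = FALSE]
  idx <- match(keys, ukeys)
  counts <- tabulate(idx, nbins = length(ukeys))
  new("PatternTable", patterns = pat, keys = ukeys,
      counts = as.integer(counts), binIndex = as.integer(idx))
}

#' Good-Turing estimate of the average missing mass
#'
#' The number of patterns observed exactly once divided by the number of
#' observations: an unbiased estimate of the stimulus-averaged probability of
#' all patterns never observed.
#'
#' @param table a \linkS4class{PatternTable}.
#' @return Scalar estimate in [0, 1].
#' @examples
#' r <- SpikeRaster(rbind(c(0, 0), c(0, 1), c(0, 1), c(1, 1)))
#' goodTuring(buildPatternTable(r))  # 2 singletons / 4 bins = 0.5
#' @export
goodTuring <- function(table) {
  nSingletons(table) / nBins(table)
}

#' Full conditional spike probability of one neuron
#'
#' P(sigma_i = 1 | sigma_\{j != i\}; s) for the Ising model: the logistic
#' function of h_i(s) + 2 * sum_\{j != i\} sigma_j J_ji. This is exact (the
#' model's full conditionals are logistic), and is the regression target of
#' pseudo-likelihood fitting.
#'
#' @param model an \linkS4class{IsingModel}.
#' @param i neuron index.
#' @param others length-N 0/1 vector; entry i is ignored.
#' @param hRow length-N field vector for the bin.
#' @return Spike probability.
#' @export
conditionalSpikeProb <- function(model, i, others, hRow) {
  J <- couplings(model)
  others <- as.numeric(others)
  others[i] <- 0
  logistic(hRow[i] + 2 * sum(others * J[, i]))
}
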