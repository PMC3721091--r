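#' @name accessors
#' @title Accessors for IsingZ classes
#' @description Slot access goes through these accessors, not `@`.
#' @param x,object an IsingZ object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
#' @rdname accessors
#' @export
setGeneric("spikeMatrix", function(x) standardGeneric("spikeMatrix"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("trialLength", function(x) standardGeneric("trialLength"))
#' @rdname accessors
#' @export
setGeneric("covariateData", function(x) standardGeneric("covariateData"))
#' @rdname accessors
#' @export
setGeneric("basisKind", function(x) standardGeneric("basisKind"))
#' @rdname accessors
#' @export
setGeneric("stimWeights", function(x) standardGeneric("stimWeights"))
#' @rdname accessors
#' @export
setGeneric("couplings", function(x) standardGeneric("couplings"))
#' @rdname accessors
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))
#' @rdname accessors
#' @export
setGeneric("patternCounts", function(x) standardGeneric("patternCounts"))
#' @rdname accessors
#' @export
setGeneric("patternKeys", function(x) standardGeneric("patternKeys"))
#' @rdname accessors
#' @export
setGeneric("nSingletons", function(x) standardGeneric("nSingletons"))
#' @rdname accessors
#' @export
setGeneric("binIndex", function(x) standardGeneric("binIndex"))
#' @rdname accessors
#' @export
setGeneric("logPartition", function(x) standardGeneric("logPartition"))
#' @rdname accessors
#' @export
setGeneric("partitionValues", function(x) standardGeneric("partitionValues"))
#' @rdname accessors
#' @export
setGeneric("seriesMethod", function(x) standardGeneric("seriesMethod"))
#' @rdname accessors
#' @export
setGeneric("mcStandardErrors", function(x) standardGeneric("mcStandardErrors"))
#' @rdname accessors
#' @export
setGeneric("operationCount", function(x) standardGeneric("operationCount"))
#' @rdname accessors
#' @export
setGeneric("missingMassValues", function(x) standardGeneric("missingMassValues"))
#' @rdname accessors
#' @export
setGeneric("chainOrdering", function(x) standardGeneric("chainOrdering"))

#' @rdname accessors
setMethod("nBins", "SpikeRaster", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nNeurons", "SpikeRaster", function(x) ncol(x@data))
#' @rdname accessors
setMethod("spikeMatrix", "SpikeRaster", function(x) x@data)
#' @rdname accessors
setMethod("binWidth", "SpikeRaster", function(x) x@binWidth)
#' @rdname accessors
setMethod("trialLength", "SpikeRaster", function(x) x@trialLength)

#' @rdname accessors
setMethod("nBins", "CovariateMatrix", function(x) nrow(x@data))
#' @rdname accessors
setMethod("covariateData", "CovariateMatrix", function(x) x@data)
#' @rdname accessors
setMethod("basisKind", "CovariateMatrix", function(x) x@basisKind)

#' @rdname accessors
setMethod("nNeurons", "IsingModel", function(x) nrow(x@J))
#' @rdname accessors
setMethod("stimWeights", "IsingModel", function(x) x@beta)
#' @rdname accessors
setMethod("couplings", "IsingModel", function(x) x@J)

#' @rdname accessors
setMethod("patterns", "PatternTable", function(x) x@patterns)
#' @rdname accessors
setMethod("patternCounts", "PatternTable", function(x) x@counts)
#' @rdname accessors
setMethod("patternKeys", "PatternTable", function(x) x@keys)
#' @rdname accessors
setMethod("nSingletons", "PatternTable", function(x) sum(x@counts == 1L))
#' @rdname accessors
setMethod("binIndex", "PatternTable", function(x) x@binIndex)
#' @rdname accessors
setMethod("nNeurons", "PatternTable", function(x) ncol(x@patterns))
#' @rdname accessors
setMethod("nBins", "PatternTable", function(x) length(x@binIndex))

#' @rdname accessors
setMethod("logPartition", "PartitionSeries", function(x) x@logValues)
#' @rdname accessors
setMethod("partitionValues", "PartitionSeries", function(x) exp(x@logValues))
#' @rdname accessors
setMethod("seriesMethod", "PartitionSeries", function(x) x@method)
#' @rdname accessors
setMethod("mcStandardErrors", "PartitionSeries", function(x) x@mcSE)
#' @rdname accessors
setMethod("operationCount", "PartitionSeries", function(x) x@opCount)
#' @rdname accessors
setMethod("nBins", "PartitionSeries", function(x) length(x@logValues))

#' @rdname accessors
setMethod("missingMassValues", "MissingMassSeries", function(x) x@values)
#' @rdname accessors
setMethod("operationCount", "MissingMassSeries", function(x) x@opCount)
#' @rdname accessors
setMethod("seriesMethod", "MissingMassSeries", function(x) x@method)
#' @rdname accessors
setMethod("nBins", "MissingMassSeries", function(x) length(x@values))

#' @rdname accessors
setMethod("chainOrdering", "ChainModel", function(x) x@ordering)
#' @rdname accessors
setMethod("nNeurons", "ChainModel", function(x) length(x@ordering))
#' @rdname accessors
setMethod("stimWeights", "ChainModel", function(x) x@stimWeights)

#' @rdname accessors
#' @export
neighborWeights <- function(x) {
  stopifnot(is(x, "ChainModel"))
  x@neighborWeights
}

setMethod("show", "SpikeRaster", function(object) {
  cat("SpikeRaster:", nBins(object), "bins x", nNeurons(object), "neurons,",
      object@binWidth * 1000, "ms bins")
  if (!is.na(object@trialLength))
    cat(",", object@trialLength, "bins/trial")
  cat("\n  mean rate:",
      format(mean(object@data) / object@binWidth, digits = 3), "Hz\n")
})

setMethod("show", "CovariateMatrix", function(object) {
  cat("CovariateMatrix:", nrow(object@data), "bins x", ncol(object@data),
      "covariates (", object@basisKind, ")\n")
})

setMethod("show", "IsingModel", function(object) {
  J <- object@J
  cat("IsingModel ({0,1} coding):", nNeurons(object), "neurons,",
      nrow(object@beta), "stimulus covariates\n  |J| range: [",
      format(min(J[upper.tri(J)]), digits = 3), ",",
      format(max(J[upper.tri(J)]), digits = 3), "]\n")
})

setMethod("show", "PatternTable", function(object) {
  cat("PatternTable:", nrow(object@patterns), "unique patterns over",
      length(object@binIndex), "bins;", nSingletons(object),
      "singletons (Good-Turing missing mass",
      format(nSingletons(object) / length(object@binIndex), digits = 3),
      ")\n")
})

setMethod("show", "PartitionSeries", function(object) {
  cat("PartitionSeries [", object@method, "]: ", length(object@logValues),
      " bins, log Z in [", format(min(object@logValues), digits = 4), ", ",
      format(max(object@logValues), digits = 4), "]\n", sep = "")
})

setMethod("show", "MissingMassSeries", function(object) {
  cat("MissingMassSeries [", object@method, "]: mean ",
      format(mean(object@values), digits = 4), ", max ",
      format(max(object@values), digits = 4), "\n", sep = "")
})

setMethod("show", "ChainModel", function(object) {
  cat("ChainModel:", nNeurons(object),
      "conditional logistic regressions, rate-ordered\n")
})

setMethod("show", "FitReport", function(object) {
  cat("FitReport:", sum(object@converged), "/", length(object@converged),
      "regressions converged\n")
})

setMethod("show", "RatioSummary", function(object) {
  cat("RatioSummary over", object@n, "bins: mean",
      format(object@mean, digits = 6), "\n  99% band {",
      format(object@quantiles[["q0.005"]], digits = 6), ",",
      format(object@quantiles[["q0.995"]], digits = 6), "}\n")
})

setMethod("show", "TrialProtocol", function(object) {
  cat("TrialProtocol:", object@nNeurons, "neurons,", object@nTrials,
      "trials x", object@trialMs, "ms at", object@binMs,
      "ms bins; jMax =", object@jMax, "\n")
})
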