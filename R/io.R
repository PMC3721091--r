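#' Read and write rasters, covariates, models and series
#'
#' Rasters and covariate matrices travel as headered tab-delimited text
#' (bins as rows; \code{#}-prefixed metadata lines carry the bin width,
#' trial length and basis kind). Models and chains travel as JSON. A binary
#' "raster set" container (RDS with named elements \code{spikes},
#' \code{covariates}, \code{bin_width}) bundles a simulation for
#' round-tripping between sessions.
#'
#' @param x object to write.
#' @param file path.
#' @name io
NULL

.writeHeadered <- function(M, file, meta) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.table(M, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

.readHeadered <- function(file) {
  lines <- readLines(file)
  metaLines <- grep("^# ", lines)
  meta <- list()
  for (l in lines[metaLines]) {
    kv <- sub("^# ", "", l)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  M <- utils::read.table(text = lines[setdiff(seq_along(lines), metaLines)],
                         header = TRUE, sep = "\t", check.names = FALSE)
  list(data = as.matrix(M), meta = meta)
}

#' @rdname io
#' @export
writeRaster <- function(x, file) {
  stopifnot(is(x, "SpikeRaster"))
  M <- spikeMatrix(x)
  colnames(M) <- paste0("n", seq_len(ncol(M)))
  .writeHeadered(M, file,
                 list(bin_width = binWidth(x),
                      trial_length = trialLength(x)))
}

#' @rdname io
#' @export
readRaster <- function(file) {
  r <- .readHeadered(file)
  tl <- suppressWarnings(as.integer(r$meta$trial_length))
  SpikeRaster(r$data, binWidth = as.numeric(r$meta$bin_width),
              trialLength = if (length(tl)) tl else NA)
}

#' @rdname io
#' @export
writeCovariates <- function(x, file) {
  stopifnot(is(x, "CovariateMatrix"))
  .writeHeadered(covariateData(x), file, list(basis_kind = basisKind(x)))
}

#' @rdname io
#' @export
readCovariates <- function(file) {
  r <- .readHeadered(file)
  CovariateMatrix(r$data, basisKind = r$meta$basis_kind)
}

#' @rdname io
#' @export
writeIsingModel <- function(x, file) {
  stopifnot(is(x, "IsingModel"))
  jsonlite::write_json(
    list(beta = stimWeights(x), J = couplings(x),
         column_labels = rownames(stimWeights(x)) %||%
           paste0("c", seq_len(nrow(stimWeights(x))))),
    file, digits = NA, matrix = "rowmajor")
}

#' @rdname io
#' @export
readIsingModel <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  IsingModel(beta = as.matrix(j$beta), J = as.matrix(j$J))
}

#' @rdname io
#' @export
writeChainModel <- function(x, file) {
  stopifnot(is(x, "ChainModel"))
  jsonlite::write_json(
    list(ordering = chainOrdering(x),
         stim_weights = stimWeights(x),
         neighbor_weights = lapply(neighborWeights(x), as.list)),
    file, digits = NA, auto_unbox = FALSE)
}

#' @rdname io
#' @export
readChainModel <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = FALSE)
  nw <- lapply(j$neighbor_weights, function(w) {
    v <- vapply(w, as.numeric, numeric(1))
    names(v) <- names(w)
    v
  })
  new("ChainModel", ordering = vapply(j$ordering, as.integer, integer(1)),
      stimWeights = lapply(j$stim_weights, function(w)
        vapply(w, as.numeric, numeric(1))),
      neighborWeights = nw)
}

#' @rdname io
#' @export
writePartitionSeries <- function(x, file) {
  stopifnot(is(x, "PartitionSeries"))
  df <- data.frame(bin = seq_len(nBins(x)), log_z = logPartition(x),
                   method = seriesMethod(x))
  if (length(mcStandardErrors(x))) df$mc_se <- mcStandardErrors(x)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname io
#' @export
readPartitionSeries <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  PartitionSeries(df$log_z, method = df$method[1],
                  mcSE = if ("mc_se" %in% names(df)) df$mc_se
                         else numeric(0))
}

#' @rdname io
#' @param raster,covariates components of a raster set.
#' @export
saveRasterSet <- function(file, raster, covariates) {
  saveRDS(list(spikes = spikeMatrix(raster),
               covariates = covariateData(covariates),
               bin_width = binWidth(raster),
               trial_length = trialLength(raster),
               basis_kind = basisKind(covariates)), file)
}

#' @rdname io
#' @export
loadRasterSet <- function(file) {
  x <- readRDS(file)
  list(raster = SpikeRaster(x$spikes, binWidth = x$bin_width,
                            trialLength = x$trial_length),
       covariates = CovariateMatrix(x$covariates,
                                    basisKind = x$basis_kind))
}
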