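#' @useDynLib IsingZ, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats runif rbinom uniroot quantile sd dbinom plogis qlogis
NULL

logistic <- function(x) plogis(x)

## log(1 + exp(x)) without overflow for large x
log1pexp <- function(x) {
  out <- x
  small <- x <= 33.3
  out[small] <- log1p(exp(x[small]))
  big <- x > 33.3 & x <= 709
  out[big] <- x[big] + exp(-x[big])
  out
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## column-wise log-sum-exp of a matrix
colLogSumExp <- function(E) {
  m <- apply(E, 2L, max)
  log(colSums(exp(sweep(E, 2L, m, "-")))) + m
}

## Run code with a temporary RNG seed, restoring the caller's RNG state.
## seed = NULL leaves the current RNG stream untouched.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## deterministic sub-seed derivation, kept below 2^31
subSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1009 * k) %% 2147483587)
}

## Index map of unique matrix rows: list(rows = unique rows, index = per-row
## pointer into rows). Per-bin quantities are computed once per unique row
## and broadcast through `index`.
uniqueRowIndex <- function(M) {
  key <- do.call(paste, c(lapply(seq_len(ncol(M)), function(j) M[, j]),
                          sep = "\r"))
  first <- !duplicated(key)
  rows <- M[first, , drop = FALSE]
  index <- match(key, key[first])
  list(rows = rows, index = index)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
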