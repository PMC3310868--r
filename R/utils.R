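## Internal helpers shared across modules.

#' Derive a reproducible substream seed from a global seed and a tag
#'
#' All stochastic stages of the pipeline draw their RNG state from
#' deterministic substreams of a single global seed, so that an entire run is
#' reproducible bit-for-bit while stages stay statistically independent.
#'
#' @param seed integer global seed.
#' @param tag character tag naming the consumer (stage, window index, ...).
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
substream_seed <- function(seed, tag) {
  ## multiplicative hash over the tag bytes, kept inside 31 bits
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(paste0(tag))) {
    h <- (h * 69069 + b) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a lagged design matrix for autoregressive least squares
#'
#' Rows correspond to targets x[(p+1):n]; columns are lag 1..p of each input
#' series, with an optional leading intercept column.
#'
#' @keywords internal
lag_matrix <- function(series_list, p, intercept = TRUE) {
  n <- length(series_list[[1]])
  stopifnot(n > p)
  cols <- lapply(series_list, function(x) stats::embed(x, p + 1)[, -1, drop = FALSE])
  X <- do.call(cbind, cols)
  if (intercept) X <- cbind(1, X)
  X
}

## fractional positions are floored to whole samples
sec_to_samples <- function(sec, fs) as.integer(floor(sec * fs))

`%||%` <- function(a, b) if (is.null(a)) b else a
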