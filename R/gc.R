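## Pairwise time-domain Granger causality.
##
## GC from X2 to X1 is the Geweke log-ratio ln(Gamma_1 / Sigma_11), where
## Gamma_1 is the prediction-error variance of the univariate AR model of X1
## and Sigma_11 the corresponding bivariate one, both estimated on identical
## effective samples. Because the univariate regressors are a subset of the
## bivariate ones, Sigma_11 <= Gamma_1 in exact arithmetic and GC >= 0;
## tiny negative round-off is clipped to zero.

#' Directed and instantaneous Granger causality for one window pair
#'
#' @param x1,x2 numeric vectors of equal length (one analysis window each).
#' @param p AR order (default 6).
#' @return an object of class `gc_estimate` with `gc_12` (X1 -> X2), `gc_21`
#'   (X2 -> X1), `instantaneous` (off-diagonal bivariate residual
#'   covariance), the residual variances, and `undefined = TRUE` when a fit
#'   was singular (collinear inputs), in which case the GC fields are `NA`.
#' @export
granger_pair <- function(x1, x2, p = 6) {
  stopifnot(p >= 1)
  out <- structure(list(gc_12 = NA_real_, gc_21 = NA_real_,
                        instantaneous = NA_real_, gamma = c(NA_real_, NA_real_),
                        sigma = c(NA_real_, NA_real_), order = p,
                        undefined = TRUE),
                   class = "gc_estimate")
  fits <- tryCatch(list(u1 = fit_ar(x1, p), u2 = fit_ar(x2, p),
                        b = fit_var2(x1, x2, p)),
                   error = function(e) {
                     if (grepl("singular", conditionMessage(e))) NULL else stop(e)
                   })
  if (is.null(fits)) return(out)
  clip0 <- function(v) if (v < 0 && v > -1e-12) 0 else v
  out$gamma <- c(fits$u1$sigma2, fits$u2$sigma2)
  out$sigma <- c(fits$b$Sigma[1, 1], fits$b$Sigma[2, 2])
  out$gc_21 <- clip0(log(fits$u1$sigma2 / fits$b$Sigma[1, 1]))
  out$gc_12 <- clip0(log(fits$u2$sigma2 / fits$b$Sigma[2, 2]))
  out$instantaneous <- fits$b$Sigma[1, 2]
  out$undefined <- !is.finite(out$gc_12) || !is.finite(out$gc_21)
  out
}

#' @export
print.gc_estimate <- function(x, ...) {
  if (x$undefined) cat("GC estimate: undefined (singular fit)\n")
  else cat(sprintf("GC estimate (p=%d): 1->2 %.4f, 2->1 %.4f, instantaneous %.4g\n",
                   x$order, x$gc_12, x$gc_21, x$instantaneous))
  invisible(x)
}

ordered_pairs <- function(regions) {
  if (length(regions) < 2) return(data.frame(from = character(0), to = character(0)))
  cmb <- utils::combn(regions, 2)
  data.frame(from = c(cmb[1, ], cmb[2, ]), to = c(cmb[2, ], cmb[1, ]))
}

#' Granger causality across all region pairs of a window set
#'
#' Applies [granger_pair()] to every QC-admitted window and every unordered
#' pair of available regions (both directions). Windows failing any QC gate
#' are skipped and accounted for; pairs involving a region marked absent are
#' omitted.
#'
#' @param ws a `window_set` from [extract_state_segments()].
#' @param p AR order (default 6).
#' @param pairs `"all"` for the full 10-pair grid, or `"frontal_posterior"`
#'   for only the four feature pairs (LF/RF -> LP/RP).
#' @return an object of class `gc_series`: long-format data frame `$table`
#'   with one row per window x directed pair (`condition`, `state`,
#'   `window`, `start_s`, `from`, `to`, `gc`, `gc_smoothed` (NA until
#'   [smooth_gc_series()]), `instantaneous`, `undefined`), plus attrition
#'   bookkeeping in `$attrition`.
#' @export
regionwise_gc <- function(ws, p = 6, pairs = c("all", "frontal_posterior")) {
  pairs <- match.arg(pairs)
  stopifnot(inherits(ws, "window_set"))
  idx <- ws$index
  admitted <- idx$stationary & idx$dw_ok & idx$consistent & idx$artifact_free
  if (!any(admitted)) {
    gates <- c(stationary = sum(!idx$stationary), dw = sum(!idx$dw_ok),
               consistency = sum(!idx$consistent), artifact = sum(!idx$artifact_free))
    stop("no windows admitted by QC; exclusions per gate: ",
         paste(sprintf("%s=%d", names(gates), gates), collapse = ", "))
  }
  regions <- ws$regions_present
  pr <- ordered_pairs(regions)
  if (pairs == "frontal_posterior") {
    keep <- pr$from %in% c("LF", "RF") & pr$to %in% c("LP", "RP")
    pr <- pr[keep, , drop = FALSE]
    if (!nrow(pr)) stop("no frontal->posterior pairs available")
  }
  rows <- vector("list", sum(admitted))
  widx <- which(admitted)
  ## unordered fits reused for both directions
  und <- unique(t(apply(cbind(pr$from, pr$to), 1, sort)))
  for (wi in seq_along(widx)) {
    w <- widx[wi]
    win <- window_data(ws, w)
    ests <- list()
    for (u in seq_len(nrow(und))) {
      r1 <- und[u, 1]; r2 <- und[u, 2]
      ests[[paste(r1, r2)]] <- granger_pair(win[, r1], win[, r2], p)
    }
    gc_v <- inst_v <- undef_v <- numeric(nrow(pr))
    for (j in seq_len(nrow(pr))) {
      r1 <- min(pr$from[j], pr$to[j]); r2 <- max(pr$from[j], pr$to[j])
      e <- ests[[paste(r1, r2)]]
      forward <- pr$from[j] == r1
      gc_v[j] <- if (forward) e$gc_12 else e$gc_21
      inst_v[j] <- e$instantaneous
      undef_v[j] <- e$undefined
    }
    rows[[wi]] <- data.frame(
      condition = idx$condition[w], state = idx$state[w], window = w,
      start_s = idx$start_s[w], from = pr$from, to = pr$to,
      gc = gc_v, gc_smoothed = NA_real_, instantaneous = inst_v,
      undefined = as.logical(undef_v))
  }
  tab <- do.call(rbind, rows)
  attrition <- c(total = nrow(idx), admitted = sum(admitted),
                 non_stationary = sum(!idx$stationary),
                 dw_failed = sum(idx$stationary & !idx$dw_ok),
                 inconsistent = sum(idx$stationary & idx$dw_ok & !idx$consistent),
                 artifact = sum(idx$stationary & idx$dw_ok & idx$consistent &
                                  !idx$artifact_free))
  structure(list(table = tab, attrition = attrition, order = p,
                 regions = regions, fs = ws$fs, smoothed = FALSE),
            class = "gc_series")
}

#' @export
print.gc_series <- function(x, ...) {
  cat(sprintf("GC series: %d rows (%d windows x %d directed pairs), order %d\n",
              nrow(x$table), length(unique(x$table$window)),
              nrow(unique(x$table[, c("from", "to")])), x$order))
  cat("  attrition:", paste(sprintf("%s=%d", names(x$attrition), x$attrition),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Trailing moving average
#'
#' Causal smoother: element `i` becomes the mean of the most recent
#' `min(n, i)` values. Length is preserved, and `n = 1` returns the series
#' unchanged. A causal (not centered) filter is used because the intended
#' application is prompt detection of state changes.
#'
#' @param x numeric vector.
#' @param n filter length (default 10).
#' @return smoothed vector of the same length.
#' @export
smooth_ma <- function(x, n = 10) {
  stopifnot(n >= 1)
  if (n == 1 || length(x) <= 1) return(x)
  cs <- cumsum(x)
  out <- numeric(length(x))
  idx <- seq_along(x)
  lo <- pmax(0, idx - n)
  out <- (cs - c(0, cs)[lo + 1]) / (idx - lo)
  out
}

#' Smooth a GC series with a trailing moving average
#'
#' Each directed pair is smoothed independently within each contiguous
#' (condition, state) block of windows, ordered by window start, mirroring
#' the moving-average filter applied to GC traces to damp artifact-driven
#' outliers.
#'
#' @param gcs a `gc_series`.
#' @param n moving-average length (default 10).
#' @return the `gc_series` with `gc_smoothed` filled in.
#' @export
smooth_gc_series <- function(gcs, n = 10) {
  stopifnot(inherits(gcs, "gc_series"))
  tab <- gcs$table
  key <- interaction(tab$condition, tab$state, tab$from, tab$to, drop = TRUE)
  for (g in levels(key)) {
    sel <- which(key == g)
    sel <- sel[order(tab$start_s[sel])]
    v <- tab$gc[sel]
    ## undefined windows carry no value; smooth over the defined ones
    def <- !is.na(v)
    v[def] <- smooth_ma(v[def], n)
    tab$gc_smoothed[sel] <- v
  }
  gcs$table <- tab
  gcs$smoothed <- TRUE
  gcs
}
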