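## Surrogate controls.
##
## (1) Phase-randomized surrogates keep each series' amplitude spectrum (and
## hence all second-order autocovariance structure) but draw independent
## Fourier phases, destroying cross-series timing; the maximum GC over a
## batch of surrogates is the per-window significance level.
## (2) The source-shift surrogate controls for volume conduction: the
## multichannel signal is unmixed into sources by SOBI (joint diagonalization
## of lagged covariance matrices), each source is circularly shifted by a
## different large offset, and the sources are remixed. Instantaneous mixing
## structure survives; genuine lagged cross-source interactions do not. If
## the y = x line relating surrogate to original GC fits well (r^2 >= 0),
## volume conduction cannot be excluded as the origin of the observed GC.

#' Phase-randomized surrogate of a time series
#'
#' Fourier transforms `x`, replaces the phases of all independent frequencies
#' with uniform(0, 2*pi) draws (DC and Nyquist bins stay real; conjugate
#' symmetry is enforced), and inverse transforms. The result has the same
#' periodogram as `x` but randomized timing.
#'
#' @param x numeric vector, length >= 8.
#' @param seed integer seed.
#' @return surrogate series of the same length.
#' @export
phase_randomize <- function(x, seed = 1) {
  n <- length(x)
  stopifnot(n >= 8)
  f <- stats::fft(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2  # bins 2..(half+1) are free
  ph <- with_seed(seed, stats::runif(half, 0, 2 * pi))
  f2 <- f
  free <- 2:(1 + half)
  f2[free] <- Mod(f[free]) * exp(1i * ph)
  f2[n + 2 - free] <- Conj(f2[free])
  Re(stats::fft(f2, inverse = TRUE)) / n
}

#' Per-direction GC significance thresholds from phase-randomized surrogates
#'
#' Generates `n_surrogates` independently phase-randomized versions of both
#' series, computes GC both ways on each surrogate pair, and returns the
#' per-direction maxima as significance levels: a real GC exceeding the
#' maximum of 19 surrogates is significant at the nominal one-sided 5% level
#' (1/(n_surrogates + 1)). Singular surrogate fits are redrawn a bounded
#' number of times, then skipped (counted in `skipped`).
#'
#' @param x1,x2 the window pair.
#' @param p AR order.
#' @param n_surrogates number of surrogates (default 19).
#' @param seed integer seed.
#' @return list with `threshold_12`, `threshold_21`, the real `gc`
#'   (`gc_estimate`), `significant_12`, `significant_21`, `skipped`.
#' @export
gc_significance_threshold <- function(x1, x2, p = 6, n_surrogates = 19, seed = 1) {
  stopifnot(n_surrogates >= 1)
  real <- granger_pair(x1, x2, p)
  g12 <- g21 <- rep(NA_real_, n_surrogates)
  skipped <- 0L
  for (s in seq_len(n_surrogates)) {
    est <- NULL
    for (try in 1:5) {
      s1 <- phase_randomize(x1, substream_seed(seed, paste0("s", s, "a", try)))
      s2 <- phase_randomize(x2, substream_seed(seed, paste0("s", s, "b", try)))
      est <- granger_pair(s1, s2, p)
      if (!est$undefined) break
    }
    if (is.null(est) || est$undefined) skipped <- skipped + 1L
    else { g12[s] <- est$gc_12; g21[s] <- est$gc_21 }
  }
  th12 <- suppressWarnings(max(g12, na.rm = TRUE))
  th21 <- suppressWarnings(max(g21, na.rm = TRUE))
  list(threshold_12 = th12, threshold_21 = th21, gc = real,
       significant_12 = isTRUE(real$gc_12 > th12),
       significant_21 = isTRUE(real$gc_21 > th21),
       skipped = skipped)
}

#' Second-order blind identification (SOBI)
#'
#' Whitens the centered channels, then jointly diagonalizes the symmetrized
#' lagged covariance matrices of the whitened data by Jacobi rotations
#' (Cardoso & Souloumiac). Sources are unique up to order and sign.
#'
#' @param signal channels x samples matrix.
#' @param lags covariance lags to diagonalize (default 1..20, which covers
#'   dynamics beyond the AR order used elsewhere in the pipeline).
#' @param max_sweeps Jacobi sweep budget (default 200; convergence is linear
#'   rather than quadratic when the noise subspace is nearly degenerate).
#' @param tol rotation-angle convergence tolerance; the default scales with
#'   the sample size (the usual SOBI stopping rule), since rotation angles
#'   within a near-degenerate noise subspace cannot settle below the
#'   estimation noise of the lagged covariances.
#' @return list with `sources` (channels x samples), `mixing` (A with
#'   signal ~ A sources), `unmixing` (W = A^-1), `means` (per-channel means
#'   removed before separation).
#' @export
sobi <- function(signal, lags = 1:20, max_sweeps = 200, tol = NULL) {
  k <- nrow(signal); n <- ncol(signal)
  if (is.null(tol)) tol <- 0.01 / sqrt(n)
  stopifnot(k >= 2, n > max(lags) * 2)
  mu <- rowMeans(signal)
  Xc <- signal - mu
  C0 <- tcrossprod(Xc) / n
  eg <- eigen(C0, symmetric = TRUE)
  if (min(eg$values) <= 0)
    stop("rank-deficient channel covariance; SOBI separation not possible")
  Wh <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  Y <- Wh %*% Xc
  M <- lapply(lags, function(l) {
    Cl <- tcrossprod(Y[, (l + 1):n, drop = FALSE], Y[, 1:(n - l), drop = FALSE]) / (n - l)
    (Cl + t(Cl)) / 2
  })
  V <- diag(k)
  for (sweep in seq_len(max_sweeps)) {
    biggest <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ## Givens angle maximizing the joint diagonality criterion
      g <- sapply(M, function(m) c(m[i, i] - m[j, j], m[i, j] + m[j, i]))
      G <- tcrossprod(g)
      ev <- eigen(G, symmetric = TRUE)
      ang <- ev$vectors[, 1]
      if (ang[1] < 0) ang <- -ang
      r <- sqrt(sum(ang^2))
      cth <- sqrt((ang[1] + r) / (2 * r))
      sth <- ang[2] / (2 * r * cth)
      if (abs(sth) > biggest) biggest <- abs(sth)
      if (abs(sth) > tol) {
        for (mi in seq_along(M)) {
          m <- M[[mi]]
          rot_i <- cth * m[i, ] + sth * m[j, ]
          rot_j <- -sth * m[i, ] + cth * m[j, ]
          m[i, ] <- rot_i; m[j, ] <- rot_j
          col_i <- cth * m[, i] + sth * m[, j]
          col_j <- -sth * m[, i] + cth * m[, j]
          m[, i] <- col_i; m[, j] <- col_j
          M[[mi]] <- m
        }
        rot_i <- cth * V[i, ] + sth * V[j, ]
        rot_j <- -sth * V[i, ] + cth * V[j, ]
        V[i, ] <- rot_i; V[j, ] <- rot_j
      }
    }
    if (biggest < tol) break
  }
  if (biggest >= tol && sweep == max_sweeps)
    warning("SOBI joint diagonalization did not fully converge; consider a different lag set")
  W <- V %*% Wh
  A <- MASS::ginv(W)
  list(sources = W %*% Xc, mixing = A, unmixing = W, means = mu)
}

#' Source-shift surrogate for volume-conduction control
#'
#' Decomposes the signal into SOBI sources, circularly shifts the n-th source
#' by `(n - 1) * T` samples (T well beyond the autocorrelation time; 100
#' samples by default), and remixes with the estimated mixing matrix. The
#' surrogate keeps the instantaneous mixing structure of the original but
#' destroys lagged cross-source interactions, so genuinely directed coupling
#' is attenuated while mixing-induced (volume-conduction) GC survives.
#'
#' @param signal channels x samples matrix.
#' @param shift T in samples (default 100).
#' @param lags SOBI lag set.
#' @return surrogate matrix of the same dimensions.
#' @export
source_shift_surrogate <- function(signal, shift = 100, lags = 1:20) {
  k <- nrow(signal); n <- ncol(signal)
  if (n <= (k - 1) * shift + 64)
    stop("signal too short for source shifting: need more than (n_sources-1)*T + one window")
  dec <- sobi(signal, lags = lags)
  S <- dec$sources
  for (i in seq_len(k)) {
    off <- ((i - 1) * shift) %% n
    if (off > 0) S[i, ] <- c(S[i, (off + 1):n], S[i, 1:off])
  }
  dec$mixing %*% S + dec$means
}

#' Goodness of fit of the y = x line between surrogate and original GC
#'
#' With `x` the original-data GC values and `y` the surrogate ones, computes
#' `r^2 = 1 - SS_res / SS_tot` for the fixed (parameter-free) prediction
#' `y_hat = x`, where `SS_res = sum((y - x)^2)` and
#' `SS_tot = sum((y - mean(y))^2)`. `r^2` may be negative: when the line does
#' not describe the data, `SS_res > SS_tot`. Verdict: volume conduction
#' cannot be excluded when `r^2 >= 0` (the line fits at least as well as the
#' mean), and is rejected otherwise.
#'
#' @param gc_orig,gc_surr equal-length numeric vectors (length >= 3).
#' @return object of class `vc_result`: `r2`, `ss_tot`, `ss_res`, `mu_y`,
#'   `verdict`, and the `(x, y)` pairs.
#' @export
volume_conduction_check <- function(gc_orig, gc_surr) {
  stopifnot(length(gc_orig) == length(gc_surr), length(gc_orig) >= 3)
  keep <- is.finite(gc_orig) & is.finite(gc_surr)
  x <- gc_orig[keep]; y <- gc_surr[keep]
  mu_y <- mean(y)
  ss_tot <- sum((y - mu_y)^2)
  ss_res <- sum((y - x)^2)
  if (ss_tot == 0) {
    return(structure(list(r2 = NA_real_, ss_tot = 0, ss_res = ss_res, mu_y = mu_y,
                          verdict = "undefined (zero-variance surrogate GC)",
                          x = x, y = y), class = "vc_result"))
  }
  r2 <- 1 - ss_res / ss_tot
  structure(list(r2 = r2, ss_tot = ss_tot, ss_res = ss_res, mu_y = mu_y,
                 verdict = if (r2 >= 0) "cannot-exclude-volume-conduction"
                           else "volume-conduction-rejected",
                 x = x, y = y), class = "vc_result")
}

#' @export
print.vc_result <- function(x, ...) {
  cat(sprintf("Volume-conduction check: r^2 = %.3f (%s)\n",
              x$r2, x$verdict))
  cat(sprintf("  SS_tot = %.4g, SS_res = %.4g, mean surrogate GC = %.4g, n = %d\n",
              x$ss_tot, x$ss_res, x$mu_y, length(x$x)))
  invisible(x)
}

#' Volume-conduction report for a whole recording
#'
#' Builds a source-shift surrogate of the recording, runs both original and
#' surrogate through identical region averaging, windowing and GC (same AR
#' order, same window scheme; QC gating is applied to the original's window
#' admission and reused for the surrogate so both sides see identical
#' processing), then evaluates the y = x criterion on the per-pair mean GC
#' values as well as on all pooled window-by-pair values.
#'
#' @param recording an `eeg_recording`.
#' @param shift source shift T in samples (default 100).
#' @param p AR order (default 6).
#' @param max_windows cap on admitted windows used per side (default 30).
#' @param ... passed to [extract_state_segments()].
#' @return list with `pairwise` (a `vc_result` on per-directed-pair means),
#'   `pooled` (a `vc_result` on all window x pair values) and the GC tables.
#' @export
volume_conduction_report <- function(recording, shift = 100, p = 6,
                                     max_windows = 30, ...) {
  surr <- recording
  surr$signal <- source_shift_surrogate(recording$signal, shift = shift)
  gc_one <- function(rec) {
    rs <- average_regions(rec, excluded = detect_bad_channels(rec))
    ws <- extract_state_segments(rs, qc = FALSE, ...)
    keep <- utils::head(seq_len(nrow(ws$index)), max_windows)
    ws$index <- ws$index[keep, , drop = FALSE]
    regionwise_gc(ws, p = p)$table
  }
  t_orig <- gc_one(recording)
  t_surr <- gc_one(surr)
  key <- paste(t_orig$from, t_orig$to)
  mean_orig <- tapply(t_orig$gc, key, mean, na.rm = TRUE)
  mean_surr <- tapply(t_surr$gc, paste(t_surr$from, t_surr$to), mean, na.rm = TRUE)
  mean_surr <- mean_surr[names(mean_orig)]
  list(pairwise = volume_conduction_check(as.numeric(mean_orig), as.numeric(mean_surr)),
       pooled = volume_conduction_check(t_orig$gc, t_surr$gc),
       gc_original = t_orig, gc_surrogate = t_surr)
}

#' Simulate a 3-channel test signal for volume-conduction experiments
#'
#' `"instantaneous"`: three independent AR(2) sources with distinct spectra,
#' mixed by a fixed non-orthogonal matrix -- all cross-channel dependence is
#' instantaneous, the situation a volume-conduction control must NOT flag as
#' interaction. `"lag_coupled"`: channel 2 is genuinely driven by channel 1
#' at lag 1 (coefficient 0.8), the situation in which source-shift surrogate
#' GC must be attenuated.
#'
#' @param seed integer seed.
#' @param type `"instantaneous"` or `"lag_coupled"`.
#' @param n samples per channel (default 12000).
#' @return 3 x n signal matrix.
#' @export
simulate_mixture_signal <- function(seed, type = c("instantaneous", "lag_coupled"),
                                    n = 12000) {
  type <- match.arg(type)
  with_seed(seed, {
    ar_src <- function(phi) as.numeric(stats::arima.sim(list(ar = phi), n + 3))
    if (type == "instantaneous") {
      S <- rbind(ar_src(c(1.2, -0.8))[1:n], ar_src(c(0.4, 0.3))[1:n],
                 ar_src(c(-0.5, -0.2))[1:n])
      A <- matrix(c(1, 0.7, 0.3, 0.5, 1, 0.6, 0.2, 0.5, 1), 3, 3)
      A %*% S
    } else {
      x1 <- ar_src(c(1.2, -0.8))
      e <- stats::rnorm(n + 3)
      x2 <- numeric(n + 3)
      for (t in 2:(n + 3)) x2[t] <- 0.3 * x2[t - 1] + 0.8 * x1[t - 1] + e[t]
      x3 <- ar_src(c(0.4, 0.3))
      rbind(x1[4:(n + 3)], x2[4:(n + 3)], x3[4:(n + 3)])
    }
  })
}

#' Volume-conduction check on a raw channel matrix
#'
#' Montage-free variant of [volume_conduction_report()] for controlled
#' experiments: computes directed GC for every ordered channel pair over
#' non-overlapping windows of the original signal and of its source-shift
#' surrogate, averages per pair, and applies the y = x criterion.
#'
#' @param signal channels x samples matrix.
#' @param p AR order.
#' @param window_samples window length in samples (default 1024).
#' @param shift source shift T (default 100).
#' @param max_windows number of windows per side (default 30).
#' @param lags SOBI lag set.
#' @return list with `check` (a `vc_result` on per-pair mean GC) and the
#'   per-pair mean vectors `gc_orig`, `gc_surr`.
#' @export
volume_conduction_matrix_check <- function(signal, p = 6, window_samples = 1024,
                                           shift = 100, max_windows = 30,
                                           lags = 1:20) {
  surr <- source_shift_surrogate(signal, shift = shift, lags = lags)
  k <- nrow(signal)
  starts <- seq(1, ncol(signal) - window_samples + 1, by = window_samples)
  starts <- utils::head(starts, max_windows)
  pair_gc <- function(sig) {
    acc <- c()
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      g12 <- g21 <- 0; m <- 0
      for (s in starts) {
        w <- s:(s + window_samples - 1)
        est <- granger_pair(sig[i, w], sig[j, w], p)
        if (!est$undefined) { g12 <- g12 + est$gc_12; g21 <- g21 + est$gc_21; m <- m + 1 }
      }
      acc <- c(acc, stats::setNames(c(g12, g21) / max(m, 1),
                                    c(paste0(i, "->", j), paste0(j, "->", i))))
    }
    acc
  }
  go <- pair_gc(signal)
  gs <- pair_gc(surr)
  list(check = volume_conduction_check(go, gs[names(go)]),
       gc_orig = go, gc_surr = gs)
}
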