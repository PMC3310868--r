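## Ingest: bad-channel screening, five-region averaging, optional 50-Hz
## notch, and extraction of state-labeled 4-s sliding windows (1-s step)
## around the LOC and ROC markers, with per-window QC gates.

#' Detect bad channels from the signal itself
#'
#' Electrode impedance is not available from file, so a signal-based proxy is
#' used: a channel is bad when its variance falls below `flat_tol`
#' (flat-lined / disconnected, possibly with a large DC offset) or when at
#' least `clip_fraction` of its samples sit at the channel extremes
#' (amplifier saturation).
#'
#' @param rec an `eeg_recording`.
#' @param flat_tol variance threshold (default 1e-6).
#' @param clip_fraction saturated-sample proportion threshold (default 0.2).
#' @return character vector of bad channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, flat_tol = 1e-6, clip_fraction = 0.2) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad <- logical(nrow(rec$signal))
  for (i in seq_len(nrow(rec$signal))) {
    x <- rec$signal[i, ]
    v <- stats::var(x)
    at_ext <- mean(x == max(x) | x == min(x))
    bad[i] <- v < flat_tol || (v >= flat_tol && at_ext >= clip_fraction)
  }
  rec$labels[bad]
}

#' Average electrodes into the five scalp regions
#'
#' Each region series is the sample-wise arithmetic mean of its non-excluded
#' member electrodes. A region whose members are all excluded (or absent from
#' the recording) is marked absent -- not silently zero -- and downstream GC
#' pairs involving it are skipped.
#'
#' @param rec an `eeg_recording`.
#' @param excluded channel labels to leave out of the averages (e.g. from
#'   [detect_bad_channels()]).
#' @return an object of class `region_signals`: `series` (samples x regions
#'   matrix, absent regions dropped), `membership`, `absent`, `fs`,
#'   `markers`.
#' @export
average_regions <- function(rec, excluded = character(0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  mont <- region_montage()
  usable <- setdiff(rec$labels, excluded)
  membership <- lapply(mont, function(m) intersect(m, usable))
  absent <- names(membership)[vapply(membership, length, 0L) == 0]
  if (length(absent))
    message("regions absent (no usable electrodes): ", paste(absent, collapse = ", "),
            "; GC pairs involving them will be omitted")
  present <- setdiff(names(mont), absent)
  series <- sapply(present, function(r) {
    rows <- match(membership[[r]], rec$labels)
    colMeans(rec$signal[rows, , drop = FALSE])
  })
  structure(list(series = series, membership = membership[present],
                 absent = absent, fs = rec$fs, markers = rec$markers,
                 filtered = FALSE),
            class = "region_signals")
}

#' @export
print.region_signals <- function(x, ...) {
  cat(sprintf("Region signals: %s (%d samples @ %g Hz)%s\n",
              paste(colnames(x$series), collapse = ", "), nrow(x$series), x$fs,
              if (x$filtered) " [50-Hz notch applied]" else ""))
  if (length(x$absent)) cat("  absent regions:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a second-order IIR notch filter at 50 Hz
#'
#' Optional line-noise removal for comparing filtered against unfiltered GC;
#' the default pipeline applies no filtering at all, since filtering can
#' disrupt the timing relations GC rests on. The output is flagged
#' `filtered` so reports can distinguish the two variants.
#'
#' @param rs a `region_signals` (fs > 100 Hz).
#' @param bw notch bandwidth in Hz (default 1).
#' @return the filtered `region_signals`.
#' @export
notch_50hz <- function(rs, bw = 1) {
  stopifnot(inherits(rs, "region_signals"), rs$fs > 100)
  w0 <- 2 * pi * 50 / rs$fs
  bwr <- 2 * pi * bw / rs$fs
  ## standard second-order notch biquad: unit gain at DC and Nyquist,
  ## -3 dB bandwidth bw around the 50-Hz zero on the unit circle
  beta <- tan(bwr / 2)
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * gain * cos(w0), 2 * gain - 1)
  for (j in seq_len(ncol(rs$series))) {
    rs$series[, j] <- as.numeric(signal::filter(b, a, rs$series[, j]))
  }
  rs$filtered <- TRUE
  rs
}

#' Cut state-labeled sliding windows around the LOC and ROC markers
#'
#' Awake windows come from the pre-LOC span (condition `LOC`) and the
#' post-ROC span (condition `ROC`). Anesthetized windows start
#' `post_induction_skip` seconds after LOC (condition `LOC`; the skip drops
#' intubation artifacts and guarantees full unconsciousness) and immediately
#' before ROC (condition `ROC`), each capped at `n_anesth_windows` windows
#' (earliest eligible for LOC, latest for ROC). Windows are `window_s`
#' seconds long, slide by `step_s`, never straddle a marker, and carry four
#' QC flags: KPSS stationarity of every region series, Durbin-Watson
#' whiteness of the univariate AR residuals, Ding consistency (minimum over
#' the four frontal->posterior pairs) and an amplitude-artifact flag (any
#' sample beyond 8 MAD of its segment).
#'
#' @param rs a `region_signals` with `LOC` and `ROC` markers.
#' @param post_induction_skip seconds of post-LOC data to discard (default 300).
#' @param n_anesth_windows cap on anesthetized windows per condition (default 300).
#' @param window_s,step_s window length and slide, seconds (defaults 4 and 1).
#' @param ar_order AR order used by the DW and consistency gates (default 6).
#' @param qc compute the QC flags (default TRUE); when FALSE all windows are
#'   admitted, for callers that gate elsewhere.
#' @param kpss_level KPSS critical level (default 0.01).
#' @param consistency_min admission threshold in percent (default 70).
#' @param seed seed for the consistency simulations.
#' @return an object of class `window_set`: `index` (one row per window:
#'   `condition`, `state`, `start`, `start_s`, QC flags, `consistency`),
#'   the region series and geometry needed to materialize any window.
#' @export
extract_state_segments <- function(rs, post_induction_skip = 300,
                                   n_anesth_windows = 300,
                                   window_s = 4, step_s = 1, ar_order = 6,
                                   qc = TRUE, kpss_level = 0.01,
                                   consistency_min = 70, seed = 1) {
  stopifnot(inherits(rs, "region_signals"))
  if (!all(c("LOC", "ROC") %in% names(rs$markers)))
    stop("markers LOC and ROC are required")
  fs <- rs$fs
  n <- nrow(rs$series)
  loc <- rs$markers[["LOC"]]; roc <- rs$markers[["ROC"]]
  if (!(loc < roc)) stop("LOC must precede ROC")
  wlen <- sec_to_samples(window_s, fs)
  step <- sec_to_samples(step_s, fs)
  skip <- sec_to_samples(post_induction_skip, fs)

  starts_in <- function(from, to) {   # half-open [from, to), 0-based starts
    if (to - from < wlen) return(integer(0))
    seq.int(from, to - wlen, by = step)
  }
  seg <- list()
  s <- starts_in(0L, loc)
  if (length(s)) seg$awake_loc <- data.frame(condition = "LOC", state = "awake", start = s)
  s <- starts_in(loc + skip, roc)
  if (length(s)) {
    s <- utils::head(s, n_anesth_windows)
    seg$anesth_loc <- data.frame(condition = "LOC", state = "anesthetized", start = s)
  }
  s <- starts_in(loc + skip, roc)
  if (length(s)) {
    s <- utils::tail(s, n_anesth_windows)
    seg$anesth_roc <- data.frame(condition = "ROC", state = "anesthetized", start = s)
  }
  s <- starts_in(roc, n)
  if (length(s)) seg$awake_roc <- data.frame(condition = "ROC", state = "awake", start = s)
  empty <- setdiff(c("awake_loc", "anesth_loc", "anesth_roc", "awake_roc"), names(seg))
  if (length(empty))
    message("segments too short for any window: ", paste(empty, collapse = ", "))
  if (!length(seg)) stop("no segment long enough for a single window")
  idx <- do.call(rbind, seg)
  rownames(idx) <- NULL
  idx$start_s <- idx$start / fs
  idx$stationary <- idx$dw_ok <- idx$consistent <- idx$artifact_free <- TRUE
  idx$consistency <- NA_real_

  ws <- structure(list(index = idx, series = rs$series, fs = fs,
                       window_samples = wlen,
                       regions_present = colnames(rs$series),
                       absent = rs$absent, markers = rs$markers,
                       window_s = window_s, step_s = step_s),
                  class = "window_set")
  if (qc) ws <- qc_windows(ws, ar_order = ar_order, kpss_level = kpss_level,
                           consistency_min = consistency_min, seed = seed)
  ws
}

#' Materialize one window of a window set
#'
#' @param ws a `window_set`.
#' @param i window index (row of `ws$index`).
#' @return samples x regions matrix of the `i`-th window.
#' @export
window_data <- function(ws, i) {
  s <- ws$index$start[i]
  ws$series[(s + 1):(s + ws$window_samples), , drop = FALSE]
}

feature_pair_regions <- function(regions) {
  fr <- intersect(c("LF", "RF"), regions)
  po <- intersect(c("LP", "RP"), regions)
  if (!length(fr) || !length(po)) return(NULL)
  expand.grid(from = fr, to = po, stringsAsFactors = FALSE)
}

qc_windows <- function(ws, ar_order = 6, kpss_level = 0.01,
                       consistency_min = 70, seed = 1) {
  idx <- ws$index
  regions <- ws$regions_present
  ## robust amplitude artifact rule, computed per marker-delimited segment
  ## (pre-LOC, LOC..ROC, post-ROC) and region: states legitimately differ in
  ## amplitude, so the 8-MAD envelope must be segment-local
  n <- nrow(ws$series)
  bounds <- sort(unique(c(0L, ws$markers[["LOC"]], ws$markers[["ROC"]], n)))
  outlier <- matrix(FALSE, n, length(regions))
  for (b in seq_len(length(bounds) - 1)) {
    rng <- (bounds[b] + 1):bounds[b + 1]
    for (j in seq_along(regions)) {
      x <- ws$series[rng, j]
      med <- stats::median(x); md <- stats::mad(x)
      if (md > 0) outlier[rng, j] <- abs(x - med) > 8 * md
    }
  }
  any_outlier <- rowSums(outlier) > 0
  fp <- feature_pair_regions(regions)
  for (w in seq_len(nrow(idx))) {
    win <- window_data(ws, w)
    rng <- (idx$start[w] + 1):(idx$start[w] + ws$window_samples)
    idx$artifact_free[w] <- !any(any_outlier[rng])
    st <- TRUE; dw <- TRUE
    for (j in seq_len(ncol(win))) {
      if (st) st <- kpss_test(win[, j], level = kpss_level)$stationary
    }
    if (st) {
      for (j in seq_len(ncol(win))) {
        f <- tryCatch(fit_ar(win[, j], ar_order), error = function(e) NULL)
        if (is.null(f)) { dw <- FALSE; break }
        if (!durbin_watson(f$residuals)$ok) { dw <- FALSE; break }
      }
    }
    idx$stationary[w] <- st
    idx$dw_ok[w] <- dw
    if (st && dw && !is.null(fp)) {
      cons <- Inf
      for (q in seq_len(nrow(fp))) {
        f <- tryCatch(fit_var2(win[, fp$from[q]], win[, fp$to[q]], ar_order),
                      error = function(e) NULL)
        cq <- if (is.null(f)) 0 else
          ar_consistency(win[, fp$from[q]], win[, fp$to[q]], f,
                         seed = substream_seed(seed, paste0("cons", w, "_", q)))
        cons <- min(cons, cq)
      }
      idx$consistency[w] <- cons
      idx$consistent[w] <- cons >= consistency_min
    }
  }
  ws$index <- idx
  ws
}

#' @export
print.window_set <- function(x, ...) {
  idx <- x$index
  cat(sprintf("Window set: %d windows of %gs (step %gs) over %s\n",
              nrow(idx), x$window_s, x$step_s,
              paste(x$regions_present, collapse = ", ")))
  tab <- table(idx$condition, idx$state)
  print(tab)
  adm <- idx$stationary & idx$dw_ok & idx$consistent & idx$artifact_free
  cat(sprintf("  admitted by QC: %d / %d\n", sum(adm), nrow(idx)))
  invisible(x)
}

#' Serialize a window set index to a columnar table
#'
#' @param ws a `window_set`.
#' @param path optional file; when given, written as tab-delimited text.
#' @return the index data frame (one row per window).
#' @export
window_table <- function(ws, path = NULL) {
  tab <- ws$index
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
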