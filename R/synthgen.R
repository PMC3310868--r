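## Synthetic state-switching EEG generator.
##
## The generator produces multichannel recordings with the statistical
## structure the GC pipeline assumes: five regional neural sources following
## stable AR(6) dynamics, with a lag-1 frontal -> posterior cross-coefficient
## that switches between an "awake" and an "anesthetized" value at the LOC and
## ROC markers. Every electrode of a region observes that region's source plus
## independent sensor noise, so region averaging remains a meaningful
## denoising step rather than a degenerate identity.

#' Standard 19-electrode 10/20 montage grouped into five scalp regions
#'
#' Regions: left frontal (LF), right frontal (RF), left posterior (LP),
#' right posterior (RP) and midline (Z).
#'
#' @return named list mapping region to its member electrode labels.
#' @export
region_montage <- function() {
  list(
    LF = c("Fp1", "F7", "F3", "T3", "C3"),
    RF = c("Fp2", "F8", "F4", "C4", "T4"),
    LP = c("T5", "P3", "O1"),
    RP = c("T6", "P4", "O2"),
    Z  = c("Fz", "Cz", "Pz")
  )
}

montage_labels <- function() unname(unlist(region_montage()))

## AR coefficients from pole locations (complex pairs at a centre frequency
## plus real poles); returns phi such that x_t = sum_k phi_k x_{t-k} + e_t.
ar_from_poles <- function(pairs, reals, fs) {
  roots <- complex(0)
  for (pr in pairs) {
    th <- 2 * pi * pr[2] / fs
    roots <- c(roots, complex(modulus = pr[1], argument = th),
               complex(modulus = pr[1], argument = -th))
  }
  roots <- c(roots, as.complex(reals))
  coef <- 1 + 0i
  for (r in roots) coef <- c(coef, 0) - c(0, r * coef)
  -Re(coef[-1])
}

## Per-region source dynamics: an alpha-band resonance plus a weaker beta
## pole pair and two small real poles, mildly varied across regions so
## sources are not exchangeable. Order is fixed at 6. Persistence is kept
## moderate (no strong pole mass near DC) so that short windows of the
## process are level-stationary in the KPSS sense -- the property the
## analysis assumes of admitted EEG segments.
source_ar_coefs <- function(fs) {
  specs <- list(
    LF = list(pairs = list(c(0.90, 10.0), c(0.55, 20)), reals = c(0.20, -0.20)),
    RF = list(pairs = list(c(0.89, 10.5), c(0.55, 19)), reals = c(0.18, -0.18)),
    LP = list(pairs = list(c(0.91, 9.5),  c(0.50, 21)), reals = c(0.15, -0.15)),
    RP = list(pairs = list(c(0.90, 9.0),  c(0.52, 22)), reals = c(0.16, -0.16)),
    Z  = list(pairs = list(c(0.88, 11.0), c(0.55, 18)), reals = c(0.19, -0.19))
  )
  lapply(specs, function(s) ar_from_poles(s$pairs, s$reals, fs))
}

## Lag-block coefficient matrix (k x k*p) of the five-source system for a
## given frontal->posterior lag-1 coupling.
source_var_matrix <- function(phi, coupling, p) {
  regions <- names(phi)
  k <- length(regions)
  A <- matrix(0, k, k * p, dimnames = list(regions, NULL))
  for (i in seq_len(k)) {
    for (lag in seq_len(p)) A[i, (lag - 1) * k + i] <- phi[[i]][lag]
  }
  for (fr in c("LF", "RF")) for (po in c("LP", "RP")) {
    A[po, match(fr, regions)] <- A[po, match(fr, regions)] + coupling
  }
  A
}

companion_matrix <- function(A) {
  k <- nrow(A); p <- ncol(A) / k
  if (p == 1) return(A)
  rbind(A, cbind(diag(k * (p - 1)), matrix(0, k * (p - 1), k)))
}

spectral_radius <- function(A) max(Mod(eigen(companion_matrix(A), only.values = TRUE)$values))

#' Configuration of the synthetic EEG generator
#'
#' Defines a three-phase recording (awake, anesthetized, awake again) sampled
#' from a stable switching vector-autoregression. During the anesthetized
#' span both frontal sources drive both posterior sources with lag-1
#' coefficient `coupling_anesth`; outside it the coefficient is
#' `coupling_awake` (0 by default, i.e. no directed interaction while awake).
#'
#' @param n_channels number of electrodes (<= 19; the standard 10/20 labels).
#' @param fs sampling rate in Hz.
#' @param durations named numeric vector, seconds of `awake_pre`, `anesth`
#'   and `awake_post` data.
#' @param coupling_awake,coupling_anesth dimensionless frontal-to-posterior
#'   VAR cross-coefficients for the two states.
#' @param ar_order_true lag order of the generating source VAR.
#' @param noise_sd innovation standard deviation of each neural source.
#' @param sensor_noise_sd standard deviation of the independent white noise
#'   each electrode adds to its regional source.
#' @param line_noise_amp amplitude of an additive 50-Hz sinusoid (random
#'   phase per channel); 0 disables it.
#' @param artifact_rate expected high-amplitude artifact bursts per minute.
#' @param artifact_amplitude burst amplitude as a multiple of the channel SD.
#' @param bad_channels labels to corrupt into near-constant, DC-offset traces
#'   (emulating bad electrode contact).
#' @param mixing optional instantaneous channel-mixing matrix (defaults to
#'   identity), for volume-conduction experiments.
#' @param seed integer seed; identical config + seed gives bit-identical data.
#' @param source_phi optional named list (`LF`, `RF`, `LP`, `RP`, `Z`) of AR
#'   coefficient vectors overriding the built-in source dynamics; the
#'   resulting VAR must be stable.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 19, fs = 256,
                       durations = c(awake_pre = 600, anesth = 1200, awake_post = 600),
                       coupling_awake = 0, coupling_anesth = 0.4,
                       ar_order_true = 6, noise_sd = 1, sensor_noise_sd = 0.5,
                       line_noise_amp = 0, artifact_rate = 0,
                       artifact_amplitude = 20,
                       bad_channels = character(0), mixing = NULL, seed = 1,
                       source_phi = NULL) {
  stopifnot(fs > 0, ar_order_true >= 1, n_channels >= 1, n_channels <= 19)
  durations <- durations[c("awake_pre", "anesth", "awake_post")]
  if (anyNA(durations) || any(durations < 0))
    stop("durations must supply non-negative awake_pre, anesth, awake_post")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (sensor_noise_sd < 0 || line_noise_amp < 0 || artifact_rate < 0 ||
      artifact_amplitude < 0)
    stop("amplitudes and rates must be non-negative")
  labels <- montage_labels()[seq_len(n_channels)]
  unknown <- setdiff(bad_channels, labels)
  if (length(unknown)) stop("bad_channels not in montage: ", paste(unknown, collapse = ", "))
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (nrow(mixing) != n_channels || ncol(mixing) != n_channels)
      stop("mixing must be a ", n_channels, "x", n_channels, " matrix")
  }
  phi <- if (is.null(source_phi)) source_ar_coefs(fs) else {
    if (!all(names(region_montage()) %in% names(source_phi)))
      stop("source_phi must name all five regions")
    source_phi[names(region_montage())]
  }
  p <- ar_order_true
  phi <- lapply(phi, function(v) c(v, rep(0, max(0, p - length(v))))[seq_len(p)])
  for (coupling in unique(c(coupling_awake, coupling_anesth))) {
    A <- source_var_matrix(phi, coupling, p)
    rho <- spectral_radius(A)
    if (rho >= 1)
      stop(sprintf("generating VAR is unstable (spectral radius %.4f >= 1) at coupling %.3f",
                   rho, coupling))
  }
  structure(list(
    n_channels = n_channels, fs = fs, durations = durations,
    coupling_awake = coupling_awake, coupling_anesth = coupling_anesth,
    ar_order_true = p, noise_sd = noise_sd, sensor_noise_sd = sensor_noise_sd,
    line_noise_amp = line_noise_amp, artifact_rate = artifact_rate,
    artifact_amplitude = artifact_amplitude, bad_channels = bad_channels,
    mixing = mixing, seed = as.integer(seed), labels = labels,
    source_phi = phi
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic EEG configuration\n")
  cat(sprintf("  %d channels @ %g Hz; durations (s): awake_pre=%g anesth=%g awake_post=%g\n",
              x$n_channels, x$fs, x$durations[1], x$durations[2], x$durations[3]))
  cat(sprintf("  coupling awake=%.3f anesthetized=%.3f; true AR order %d; seed %d\n",
              x$coupling_awake, x$coupling_anesth, x$ar_order_true, x$seed))
  invisible(x)
}

#' Generate a synthetic multichannel recording
#'
#' Simulates the five-source switching VAR defined by `config`, projects the
#' sources onto the electrodes of their regions (plus independent sensor
#' noise), then applies, in order: the optional instantaneous mixing matrix,
#' 50-Hz line noise, bad-channel corruption and artifact bursts. The
#' generating state sequence, coupling values, bad channels and artifact
#' intervals are stored in `$truth`.
#'
#' @param config a [sim_config()].
#' @return an object of class `eeg_recording` with fields `signal`
#'   (channels x samples), `labels`, `fs`, `markers` (0-based sample indices
#'   of `LOC` and `ROC`) and `truth`.
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  seg <- vapply(config$durations, sec_to_samples, integer(1), fs = fs)
  n <- sum(seg)
  if (n <= config$ar_order_true * 10)
    stop("recording too short for the configured AR order")
  state <- rep(c(0L, 1L, 0L), times = seg)
  loc <- seg[[1]]
  roc <- seg[[1]] + seg[[2]]
  regions <- names(region_montage())
  p <- config$ar_order_true
  A0 <- source_var_matrix(config$source_phi, config$coupling_awake, p)
  A1 <- source_var_matrix(config$source_phi, config$coupling_anesth, p)

  sources <- with_seed(substream_seed(config$seed, "sources"), {
    innov <- matrix(stats::rnorm(5L * n, sd = config$noise_sd), nrow = 5L)
    var_switch_sim_cpp(A0, A1, innov, state)
  })
  rownames(sources) <- regions

  membership <- region_of_label(config$labels)
  signal <- with_seed(substream_seed(config$seed, "sensors"), {
    s <- sources[membership, , drop = FALSE] +
      matrix(stats::rnorm(config$n_channels * n, sd = config$sensor_noise_sd),
             nrow = config$n_channels)
    rownames(s) <- config$labels
    s
  })

  if (!is.null(config$mixing)) signal <- config$mixing %*% signal

  if (config$line_noise_amp > 0) {
    signal <- with_seed(substream_seed(config$seed, "line"), {
      tt <- (seq_len(n) - 1) / fs
      for (i in seq_len(nrow(signal))) {
        phase <- stats::runif(1, 0, 2 * pi)
        signal[i, ] <- signal[i, ] +
          config$line_noise_amp * sin(2 * pi * 50 * tt + phase)
      }
      signal
    })
  }

  if (length(config$bad_channels)) {
    signal <- with_seed(substream_seed(config$seed, "bad"), {
      for (lb in config$bad_channels) {
        signal[match(lb, config$labels), ] <- 500 + stats::rnorm(n, sd = 1e-4)
      }
      signal
    })
  }

  rec <- structure(list(
    signal = signal, labels = config$labels, fs = fs,
    markers = c(LOC = loc, ROC = roc),
    truth = list(state = state, coupling_awake = config$coupling_awake,
                 coupling_anesth = config$coupling_anesth,
                 bad_channels = config$bad_channels,
                 artifacts = data.frame(start = integer(0), end = integer(0)))
  ), class = "eeg_recording")

  if (config$artifact_rate > 0) {
    rec <- inject_artifacts(rec, rate = config$artifact_rate,
                            amplitude = config$artifact_amplitude,
                            seed = substream_seed(config$seed, "artifacts"))
  }
  rec
}

region_of_label <- function(labels) {
  mont <- region_montage()
  out <- character(length(labels))
  for (r in names(mont)) out[labels %in% mont[[r]]] <- r
  if (any(out == "")) stop("labels outside the 10/20 montage: ",
                           paste(labels[out == ""], collapse = ", "))
  out
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz\n",
              nrow(x$signal), ncol(x$signal), x$fs))
  cat("  markers:", paste(sprintf("%s=%d", names(x$markers), x$markers), collapse = ", "), "\n")
  invisible(x)
}

#' Inject sparse high-amplitude artifact bursts
#'
#' Adds short (0.1-0.5 s) square bursts at Poisson-distributed times across
#' all channels, emulating diathermy-like contamination. Burst intervals are
#' appended to `truth$artifacts` so downstream artifact detection can be
#' validated against ground truth.
#'
#' @param recording an `eeg_recording`.
#' @param rate expected bursts per minute (0 returns the input unchanged).
#' @param amplitude burst height as a multiple of each channel's standard
#'   deviation.
#' @param seed integer seed.
#' @return the modified recording.
#' @export
inject_artifacts <- function(recording, rate, amplitude = 20, seed = 1) {
  stopifnot(inherits(recording, "eeg_recording"), rate >= 0)
  if (rate == 0) return(recording)
  n <- ncol(recording$signal)
  fs <- recording$fs
  with_seed(seed, {
    n_events <- stats::rpois(1, rate * n / fs / 60)
    if (n_events > 0) {
      starts <- sort(sample.int(n, n_events, replace = TRUE)) - 1L
      durs <- pmax(1L, sec_to_samples(stats::runif(n_events, 0.1, 0.5), fs))
      sds <- apply(recording$signal, 1, stats::sd)
      events <- data.frame(start = integer(0), end = integer(0))
      for (e in seq_len(n_events)) {
        s0 <- starts[e]
        s1 <- min(n - 1L, s0 + durs[e] - 1L)
        sgn <- sample(c(-1, 1), 1)
        idx <- (s0 + 1L):(s1 + 1L)
        recording$signal[, idx] <- recording$signal[, idx] + sgn * amplitude * sds
        events <- rbind(events, data.frame(start = s0, end = s1))
      }
      recording$truth$artifacts <- rbind(recording$truth$artifacts, events)
    }
    recording
  })
}
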