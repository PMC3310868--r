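## Recording I/O: a plain delimited channel-matrix text format (one row per
## sample, header of channel labels) and minimal 16-bit EDF. Both carry a
## sidecar JSON (<path>.json) with the sampling rate, event markers and, for
## synthetic data, the generator truth. No R EDF package is available in this
## toolchain, so the EDF container is read and written directly; only the
## plain-EDF subset needed for round-tripping continuous multichannel data is
## supported (no EDF+ annotations).

normalize_labels <- function(labels) {
  std <- montage_labels()
  idx <- match(tolower(labels), tolower(std))
  if (anyNA(idx))
    stop("unknown channel labels (not 10/20): ",
         paste(labels[is.na(idx)], collapse = ", "))
  std[idx]
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(recording, path, n_samples) {
  meta <- list(fs = recording$fs,
               n_samples = n_samples,
               markers = as.list(recording$markers))
  if (!is.null(recording$truth)) {
    tr <- recording$truth
    tr$state <- NULL  # reconstructible from the markers
    meta$truth <- tr
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a recording to disk
#'
#' `format = "matrix"` writes a tab-delimited text matrix (header = channel
#' labels, one row per sample) and `format = "edf"` a 16-bit EDF file with
#' 1-second data records. Both formats get a `<path>.json` sidecar holding
#' the sampling rate, markers and generator truth (if present).
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @param format `"matrix"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(recording, "eeg_recording"))
  if (format == "matrix") {
    m <- t(recording$signal)
    colnames(m) <- recording$labels
    utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    write_sidecar(recording, path, ncol(recording$signal))
  } else {
    write_edf(recording, path)
    write_sidecar(recording, path, ncol(recording$signal))
  }
  invisible(path)
}

pad8 <- function(x, width) formatC(as.character(x), width = width, flag = "-")

write_edf <- function(recording, path) {
  sig <- recording$signal
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  nch <- nrow(sig)
  n <- ncol(sig)
  spr <- as.integer(fs)                      # samples per 1-s record
  n_rec <- as.integer(ceiling(n / spr))
  pad <- n_rec * spr - n
  if (pad > 0) sig <- cbind(sig, matrix(0, nch, pad))

  ## physical range fields are 8 ASCII chars in the header; choose the
  ## printed 8-char representation first (rounded outward so the range still
  ## covers the data) and scale with its parsed value, so any conforming
  ## reader recovers the samples to full quantization precision
  fmt_phys <- function(v, up) {
    for (d in 6:0) {
      r <- if (up) ceiling(v * 10^d) / 10^d else floor(v * 10^d) / 10^d
      s <- sprintf("%.*f", d, r)
      if (nchar(s) <= 8) return(s)
    }
    sprintf("%.0f", if (up) ceiling(v) else floor(v))
  }
  pmin_s <- vapply(apply(sig, 1, min), fmt_phys, "", up = FALSE)
  pmax_s <- vapply(apply(sig, 1, max), fmt_phys, "", up = TRUE)
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  pmax_s[flat] <- sub("^\\s+", "", formatC(pmax[flat], format = "g", digits = 7))
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad8(x, width), con, nchars = width, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (nch + 1L), 8); wr("", 44); wr(n_rec, 8); wr(1L, 8); wr(nch, 4)
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32)
  fields <- list(recording$labels, rep("AgAgCl electrode", nch), rep("uV", nch),
                 pmin_s, pmax_s,
                 rep(dmin, nch), rep(dmax, nch), rep("", nch), rep(spr, nch),
                 rep("", nch))
  for (f in seq_along(fields)) for (ch in seq_len(nch)) wr(fields[[f]][ch], widths[f])

  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nch)) {
      dig <- as.integer(round((sig[ch, idx] - pmin[ch]) / scale[ch]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8)); nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)

  sig <- matrix(0, nch, n_rec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little")
      sig[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        (dig - dmin[ch]) * scale[ch] + pmin[ch]
    }
  }
  list(signal = sig, labels = labels, fs = spr[1] / rec_dur)
}

#' Read a recording from disk
#'
#' Reads either the delimited matrix format or EDF (as written by
#' [write_recording()], or any plain continuous EDF). Channel labels are
#' normalized case-insensitively against the 10/20 set; unknown labels are an
#' error, while missing electrodes are simply absent from the returned
#' recording. The signal is returned exactly as stored -- no frequency
#' filtering is applied at read time, so the timing relations GC depends on
#' are untouched.
#'
#' @param path file path.
#' @param format `"auto"` (sniff), `"matrix"` or `"edf"`.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "matrix", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    head <- readBin(path, "raw", n = 8)
    format <- if (identical(rawToChar(head[1]), "0")) "edf" else "matrix"
  }
  meta <- read_sidecar(path)
  if (format == "matrix") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    labels <- normalize_labels(colnames(tab))
    signal <- t(as.matrix(tab))
    rownames(signal) <- labels
    if (is.null(meta) || is.null(meta$fs)) stop("sampling rate missing: no sidecar ", sidecar_path(path))
    fs <- meta$fs
  } else {
    e <- read_edf(path)
    labels <- normalize_labels(e$labels)
    signal <- e$signal
    rownames(signal) <- labels
    fs <- if (!is.null(meta) && !is.null(meta$fs)) meta$fs else e$fs
    if (!is.null(meta) && !is.null(meta$n_samples) && meta$n_samples <= ncol(signal))
      signal <- signal[, seq_len(meta$n_samples), drop = FALSE]
  }
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  markers <- integer(0)
  truth <- NULL
  if (!is.null(meta)) {
    if (!is.null(meta$markers)) {
      markers <- unlist(meta$markers)
      bad <- markers < 0 | markers >= ncol(signal)
      if (any(bad)) stop("marker indices outside the recording: ",
                         paste(names(markers)[bad], collapse = ", "))
    }
    truth <- meta$truth
  }
  structure(list(signal = signal, labels = labels, fs = fs,
                 markers = markers, truth = truth),
            class = "eeg_recording")
}
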