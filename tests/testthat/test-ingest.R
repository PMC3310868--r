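test_that("bad-channel detection finds generator-corrupted and constant channels", {
  cfg <- sim_config(durations = c(awake_pre = 3, anesth = 6, awake_post = 3),
                    bad_channels = "T5", seed = 6)
  rec <- generate_recording(cfg)
  expect_identical(detect_bad_channels(rec), "T5")

  clean <- generate_recording(sim_config(
    durations = c(awake_pre = 3, anesth = 6, awake_post = 3), seed = 6))
  expect_identical(detect_bad_channels(clean), character(0))

  allconst <- clean
  allconst$signal[] <- 7
  expect_identical(detect_bad_channels(allconst), clean$labels)
})

test_that("region averaging is the arithmetic mean of non-excluded members", {
  rec <- small_recording()
  rs <- average_regions(rec)
  lf_rows <- match(region_montage()$LF, rec$labels)
  expect_equal(rs$series[, "LF"], colMeans(rec$signal[lf_rows, ]),
               ignore_attr = TRUE)
  # exclusion rule: LP with O1 excluded averages T5 and P3 only
  rs2 <- average_regions(rec, excluded = "O1")
  expect_identical(rs2$membership$LP, c("T5", "P3"))
  expect_equal(rs2$series[, "LP"],
               colMeans(rec$signal[match(c("T5", "P3"), rec$labels), ]),
               ignore_attr = TRUE)
})

test_that("a region with no usable electrodes is absent, and GC pairs drop it", {
  rec <- small_recording()
  expect_message(rs <- average_regions(rec, excluded = c("T6", "P4", "O2")),
                 "RP")
  expect_identical(rs$absent, "RP")
  expect_false("RP" %in% colnames(rs$series))
  ws <- extract_state_segments(rs, qc = FALSE)
  gcs <- regionwise_gc(ws, p = 6)
  expect_equal(nrow(unique(gcs$table[, c("from", "to")])), 12)  # C(4,2) pairs, 2 directions
  expect_false(any(gcs$table$from == "RP" | gcs$table$to == "RP"))
})

test_that("region averaging commutes with scalar scaling", {
  rec <- small_recording()
  scaled <- rec
  scaled$signal <- 3.7 * rec$signal
  expect_equal(average_regions(scaled)$series, 3.7 * average_regions(rec)$series)
})

test_that("window arithmetic: counts, skip rule and anesthetized cap", {
  # 10-s segment at 256 Hz -> 7 windows (starts 0..6 s)
  rec <- small_recording()
  rs <- average_regions(rec)
  rs10 <- rs
  rs10$series <- rs$series[1:(10 * 256), , drop = FALSE]
  rs10$markers <- c(LOC = 0L, ROC = 10L * 256L)  # segment is half-open [LOC, ROC)
  ws10 <- suppressMessages(
    extract_state_segments(rs10, post_induction_skip = 0, qc = FALSE))
  expect_equal(sum(ws10$index$condition == "LOC" & ws10$index$state == "anesthetized"), 7)
  expect_equal(diff(sort(unique(ws10$index$start))), rep(256, 6))

  # skip: first anesthetized LOC window starts at or after LOC + 300 s
  ws <- small_window_set()
  idx <- ws$index
  loc <- rs$markers["LOC"]
  an_loc <- idx[idx$condition == "LOC" & idx$state == "anesthetized", ]
  expect_true(all(an_loc$start >= loc + 300 * 256))
  # no window straddles a marker
  roc <- rs$markers["ROC"]
  expect_false(any(idx$start < loc & idx$start + ws$window_samples > loc))
  expect_false(any(idx$start < roc & idx$start + ws$window_samples > roc))

  # cap: 86 eligible anesthetized starts here, capped at 50 keeps the earliest
  ws_cap <- extract_state_segments(rs, post_induction_skip = 300,
                                   n_anesth_windows = 50, qc = FALSE)
  an <- ws_cap$index[ws_cap$index$condition == "LOC" &
                       ws_cap$index$state == "anesthetized", ]
  expect_equal(nrow(an), 50)
  expect_equal(an$start, sort(an$start))
  expect_equal(min(an$start), unname(loc + 300 * 256))
})

test_that("window bookkeeping matches eligible starts per segment", {
  ws <- small_window_set()
  rs_n <- nrow(ws$series)
  loc <- ws$markers["LOC"]; roc <- ws$markers["ROC"]
  eligible <- function(len_samples) max(0, (len_samples - ws$window_samples) %/% 256 + 1)
  n_awake <- eligible(loc) + eligible(rs_n - roc)
  expect_equal(sum(ws$index$state == "awake"), n_awake)
})

test_that("50-Hz notch removes line noise and little else, and is off by default", {
  fs <- 256
  t <- (0:(20 * fs - 1)) / fs
  rec <- small_recording()
  rs <- average_regions(rec)
  rs$series <- rs$series[seq_along(t), , drop = FALSE]

  sine <- rs; sine$series[] <- sin(2 * pi * 50 * t)
  out <- notch_50hz(sine)
  keep <- (5 * fs):length(t)   # discard filter transient
  expect_lt(sqrt(mean(out$series[keep, 1]^2)), 0.05 * sqrt(mean(sine$series[keep, 1]^2)))
  expect_true(out$filtered)

  dc <- rs; dc$series[] <- 2.5
  outdc <- notch_50hz(dc)
  expect_equal(outdc$series[keep, 1], rep(2.5, length(keep)),
               tolerance = 1e-6, ignore_attr = TRUE)

  set.seed(2)
  wn <- rs; wn$series[] <- rnorm(length(rs$series))
  outwn <- notch_50hz(wn)
  pow_band <- function(x, lo, hi) {
    sp <- spec.pgram(x, plot = FALSE, taper = 0)
    sum(sp$spec[sp$freq * fs >= lo & sp$freq * fs <= hi])
  }
  ratio_outside <- pow_band(outwn$series[, 1], 0, 45) /
    pow_band(wn$series[, 1], 0, 45)
  expect_gt(ratio_outside, 0.95)
})
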