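test_that("same config and seed give bit-identical recordings", {
  cfg <- sim_config(durations = c(awake_pre = 10, anesth = 20, awake_post = 10),
                    seed = 42)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$markers, r2$markers)
})

test_that("durations and markers are honored to the sample", {
  cfg <- sim_config(durations = c(awake_pre = 12.5, anesth = 30, awake_post = 7.25),
                    fs = 256, seed = 3)
  rec <- generate_recording(cfg)
  expect_equal(ncol(rec$signal), floor(12.5 * 256) + 30 * 256 + floor(7.25 * 256))
  expect_equal(unname(rec$markers["LOC"]), floor(12.5 * 256))
  expect_lt(rec$markers["LOC"], rec$markers["ROC"])
  st <- rec$truth$state
  expect_true(all(st[seq_len(rec$markers["LOC"])] == 0))
  expect_true(all(st[(rec$markers["LOC"] + 1):rec$markers["ROC"]] == 1))
  expect_true(all(st[(rec$markers["ROC"] + 1):length(st)] == 0))
})

test_that("zero coupling leaves across-region signals uncorrelated at lags 1..6", {
  cfg <- sim_config(durations = c(awake_pre = 0, anesth = 120, awake_post = 0),
                    coupling_anesth = 0, seed = 8)
  rec <- generate_recording(cfg)
  rs <- average_regions(rec)
  n <- nrow(rs$series)
  # prewhiten each region (AR(6) innovations) so the 4/sqrt(n) white-noise
  # band applies to the cross-correlations
  wh <- apply(rs$series, 2, function(x) fit_ar(x, 6)$residuals)
  for (pair in list(c("LF", "LP"), c("RF", "RP"), c("Z", "LP"))) {
    cc <- ccf(wh[, pair[1]], wh[, pair[2]], lag.max = 6, plot = FALSE)$acf[, 1, 1]
    expect_true(all(abs(cc) < 4 / sqrt(n)),
                info = paste("pair", paste(pair, collapse = "-")))
  }
})

test_that("two-node closed form ln(1 + c^2) holds, against a long-run oracle", {
  # long-run variance-ratio oracle at n = 10^6
  cp <- coupled_pair(1e6, c = 0.5, seed = 2)
  oracle <- gc_oracle(cp$x1, cp$x2, p = 1)
  expect_equal(oracle$gc_21, log(1.25), tolerance = 0.01)
  # the estimator agrees with the closed form on the same system
  est <- granger_pair(cp$x1[1:2e5], cp$x2[1:2e5], p = 6)
  expect_equal(est$gc_21, log(1.25), tolerance = 0.02)
  expect_lt(est$gc_12, 0.01)
})

test_that("unstable source dynamics are rejected with the spectral radius named", {
  phi_bad <- list(LF = c(1.05), RF = 0.5, LP = 0.5, RP = 0.5, Z = 0.5)
  expect_error(sim_config(ar_order_true = 1, source_phi = phi_bad),
               "spectral radius")
  expect_error(sim_config(noise_sd = -1), "positive")
  expect_error(sim_config(artifact_rate = -2), "non-negative")
})

test_that("bad channels are emitted near-constant and listed in truth", {
  cfg <- sim_config(durations = c(awake_pre = 5, anesth = 10, awake_post = 5),
                    bad_channels = c("T5", "O2"), seed = 4)
  rec <- generate_recording(cfg)
  for (ch in c("T5", "O2")) {
    x <- rec$signal[ch, ]
    expect_lt(var(x), 1e-6)
    expect_gt(abs(mean(x)), 100)
  }
  expect_identical(rec$truth$bad_channels, c("T5", "O2"))
})

test_that("artifact injection: identity at rate 0, Poisson counts otherwise", {
  rec <- small_recording()
  expect_identical(inject_artifacts(rec, rate = 0), rec)
  # 2-minute slice, rate 30/min -> Poisson(60) burst counts
  slice <- rec
  slice$signal <- rec$signal[, 1:(120 * 256)]
  counts <- vapply(1:100, function(s)
    nrow(inject_artifacts(slice, rate = 30, seed = s)$truth$artifacts), 0L)
  lim <- qpois(c(5e-4, 1 - 5e-4), 60)
  expect_true(all(counts >= lim[1] & counts <= lim[2]))
  expect_equal(mean(counts), 60, tolerance = 0.05)
})

test_that("injected bursts are exactly the windows the artifact gate flags", {
  cfg <- sim_config(durations = c(awake_pre = 0, anesth = 120, awake_post = 0),
                    seed = 21)
  rec <- generate_recording(cfg)
  rec2 <- inject_artifacts(rec, rate = 2, amplitude = 50, seed = 77)
  ev <- rec2$truth$artifacts
  expect_gt(nrow(ev), 0)
  rs <- average_regions(rec2)
  ws <- extract_state_segments(rs, post_induction_skip = 0, qc = FALSE)
  ws <- gcdoa:::qc_windows(ws, seed = 1)
  wlen <- ws$window_samples
  overlaps <- vapply(seq_len(nrow(ws$index)), function(w) {
    s <- ws$index$start[w]
    any(ev$start <= s + wlen - 1 & ev$end >= s)
  }, TRUE)
  expect_identical(unname(!ws$index$artifact_free), unname(overlaps))
})

test_that("anesthetized frontal->posterior coupling raises GC relative to awake", {
  ws <- small_window_set()
  gcs <- regionwise_gc(ws, p = 6, pairs = "frontal_posterior")
  tab <- gcs$table
  an <- tab$gc[tab$state == "anesthetized"]
  aw <- tab$gc[tab$state == "awake"]
  expect_gt(mean(an, na.rm = TRUE), mean(aw, na.rm = TRUE))
  f <- compare_performance(an[!is.na(an)], aw[!is.na(aw)])
  expect_lt(f$p, 0.05)
})
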