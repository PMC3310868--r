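make_features <- function(n_aw = 60, n_an = 60, sep = 3, seed = 1, cond = "LOC") {
  set.seed(seed)
  f <- rbind(matrix(rnorm(n_aw * 4, 0), ncol = 4),
             matrix(rnorm(n_an * 4, sep), ncol = 4))
  out <- data.frame(window = seq_len(n_aw + n_an),
                    label = rep(c("awake", "anesthetized"), c(n_aw, n_an)),
                    condition = cond, start_s = seq_len(n_aw + n_an))
  out[c("LF.LP", "RF.LP", "LF.RP", "RF.RP")] <- f
  attr(out, "feature_cols") <- c("LF.LP", "RF.LP", "LF.RP", "RF.RP")
  out
}

test_that("feature building conserves window counts and carries labels", {
  ws <- small_window_set()
  gcs <- smooth_gc_series(regionwise_gc(ws, p = 6))
  feats <- build_features(gcs)
  adm <- sum(ws$index$stationary & ws$index$dw_ok & ws$index$consistent &
               ws$index$artifact_free)
  expect_equal(nrow(feats), adm)
  expect_setequal(attr(feats, "feature_cols"), c("LF.LP", "RF.LP", "LF.RP", "RF.RP"))
  expect_true(all(feats$label %in% c("awake", "anesthetized")))
})

test_that("an absent posterior region halves the feature dimensionality", {
  rec <- small_recording()
  rs <- suppressMessages(average_regions(rec, excluded = c("T6", "P4", "O2")))
  ws <- extract_state_segments(rs, qc = FALSE)
  gcs <- smooth_gc_series(regionwise_gc(ws, p = 6))
  feats <- suppressMessages(build_features(gcs))
  expect_setequal(attr(feats, "feature_cols"), c("LF.LP", "RF.LP"))
})

test_that("bootstrap split follows the N_train rule and is reproducible", {
  sp <- bootstrap_split(300, 300, seed = 1, repetition = 1)
  expect_equal(sp$n_train, 100)
  expect_equal(length(sp$test_awake), 200)
  expect_equal(length(sp$test_anesth), 200)

  sp2 <- bootstrap_split(50, 300, seed = 1, repetition = 1)
  expect_equal(sp2$n_train, 40)
  expect_equal(length(sp2$test_awake), 10)
  expect_equal(length(sp2$test_anesth), 260)

  expect_identical(bootstrap_split(80, 90, seed = 7, repetition = 3),
                   bootstrap_split(80, 90, seed = 7, repetition = 3))
  expect_false(identical(bootstrap_split(80, 90, seed = 7, repetition = 3)$train_awake,
                         bootstrap_split(80, 90, seed = 7, repetition = 4)$train_awake))
  # no window in both train and test; union covers the class
  expect_length(intersect(sp$train_awake, sp$test_awake), 0)
  expect_setequal(c(sp$train_awake, sp$test_awake), 1:300)
  expect_error(bootstrap_split(3, 300), "n_awake")
})

test_that("all three classifiers separate wide-margin classes perfectly", {
  feats <- make_features(sep = 8, seed = 2)
  X <- feats[, attr(feats, "feature_cols")]
  tr <- c(1:30, 61:90); te <- setdiff(1:120, tr)
  for (m in c("LDA", "SVM_L", "SVM_NL")) {
    pred <- train_and_classify(X[tr, ], feats$label[tr], X[te, ], m)
    expect_equal(as.character(pred), feats$label[te], info = m)
  }
  expect_error(train_and_classify(X[1:30, ], feats$label[1:30], X[te, ], "LDA"),
               "both classes")
})

test_that("LDA agrees with the MASS reference on a generic problem", {
  feats <- make_features(sep = 1.5, seed = 3)
  X <- feats[, attr(feats, "feature_cols")]
  tr <- c(1:40, 61:100); te <- setdiff(1:120, tr)
  ours <- train_and_classify(X[tr, ], feats$label[tr], X[te, ], "LDA")
  ref <- MASS::lda(X[tr, ], grouping = feats$label[tr], prior = c(0.5, 0.5))
  theirs <- predict(ref, X[te, ])$class
  expect_equal(as.character(ours), as.character(theirs))
})

test_that("evaluation metrics reproduce hand-computed confusion arithmetic", {
  truth <- rep(c("awake", "anesthetized"), each = 10)
  pred <- truth
  pred[10] <- "anesthetized"          # 9/10 awake correct
  pred[11:12] <- "awake"              # 8/10 anesthetized correct
  ev <- evaluate_predictions(pred, truth)
  expect_identical(ev$sensitivity, 0.9)
  expect_identical(ev$specificity, 0.8)
  expect_equal(ev$average_accuracy, 0.85)
  expect_identical(c(ev$TotP, ev$TotN, ev$TruP, ev$TruN), c(10L, 10L, 9L, 8L))

  perfect <- evaluate_predictions(truth, truth)
  expect_identical(perfect$average_accuracy, 1)

  all_an <- evaluate_predictions(rep("anesthetized", 20), truth)
  expect_identical(all_an$sensitivity, 0)
  expect_identical(all_an$specificity, 1)
  expect_identical(all_an$average_accuracy, 0.5)

  one_class <- evaluate_predictions(rep("awake", 5), rep("awake", 5))
  expect_true(is.na(one_class$specificity))
})

test_that("metrics are invariant to permutations of test order", {
  set.seed(4)
  truth <- sample(c("awake", "anesthetized"), 50, replace = TRUE)
  pred <- sample(c("awake", "anesthetized"), 50, replace = TRUE)
  perm <- sample(50)
  e1 <- evaluate_predictions(pred, truth)
  e2 <- evaluate_predictions(pred[perm], truth[perm])
  expect_identical(e1, e2)
})

test_that("two-group ANOVA equals the squared pooled t-test and handles degeneracy", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(15 + i); b <- rnorm(12 + i, mean = runif(1, -1, 1))
    cp <- compare_performance(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(cp$F, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(cp$p, tt$p.value, tolerance = 1e-8)
  }
  same <- compare_performance(rep(0.9, 10), rep(0.9, 10))
  expect_identical(c(same$F, same$p), c(0, 1))
  sep <- compare_performance(rnorm(30), rnorm(30, 10))
  expect_lt(sep$p, 0.05)
})

test_that("bootstrap study aggregates per-repetition metrics coherently", {
  feats <- make_features(n_aw = 40, n_an = 55, sep = 6, seed = 6)
  rep_ <- bootstrap_study(feats, B = 25, seed = 3)
  expect_equal(nrow(rep_$per_repetition), 25 * 3)
  expect_equal(rep_$n_train, 32)
  expect_true(all(rep_$summary$mean >= 0 & rep_$summary$mean <= 1))
  acc <- rep_$summary[rep_$summary$metric == "average_accuracy", "mean"]
  expect_true(all(acc > 0.95))       # wide margin: everything near-perfect
  # determinism of the full study
  rep2 <- bootstrap_study(feats, B = 25, seed = 3)
  expect_identical(rep_$per_repetition, rep2$per_repetition)
})
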