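## Bootstrap classification study.
##
## Features are the four smoothed frontal -> posterior GC values per admitted
## window (LF->LP, RF->LP, LF->RP, RF->RP); if a posterior region is absent
## its two components are dropped. Per repetition, N_train windows per class
## are drawn without replacement for training (so the test set -- "the
## remaining windows" -- is well defined) and the B repetitions provide the
## resampling distribution. Awake is the positive class: sensitivity is the
## fraction of awake windows recognized, specificity the fraction of
## anesthetized windows recognized, and average accuracy their mean, so both
## error types carry equal weight regardless of class imbalance.

FEATURE_PAIRS <- data.frame(from = c("LF", "RF", "LF", "RF"),
                            to   = c("LP", "LP", "RP", "RP"))

#' Build feature vectors from a smoothed GC series
#'
#' One row per admitted window: the smoothed GC values of the available
#' frontal -> posterior pairs, the class label and the condition.
#'
#' @param gcs a `gc_series` (smoothed; raw GC is used with a warning
#'   otherwise).
#' @return data frame with feature columns (`LF.LP`, `RF.LP`, `LF.RP`,
#'   `RF.RP`, as available), `label`, `condition`, `window`, `start_s`.
#' @export
build_features <- function(gcs) {
  stopifnot(inherits(gcs, "gc_series"))
  tab <- gcs$table
  value_col <- if (gcs$smoothed) "gc_smoothed" else "gc"
  if (!gcs$smoothed) warning("GC series not smoothed; using raw GC values")
  avail <- FEATURE_PAIRS[FEATURE_PAIRS$from %in% gcs$regions &
                           FEATURE_PAIRS$to %in% gcs$regions, , drop = FALSE]
  if (!nrow(avail)) stop("no frontal->posterior pairs available for features")
  if (nrow(avail) < 4)
    message("feature dimensionality reduced to ", nrow(avail),
            " (absent regions: ", paste(setdiff(unique(c(FEATURE_PAIRS$from, FEATURE_PAIRS$to)),
                                                gcs$regions), collapse = ", "), ")")
  sel <- tab[tab$from == avail$from[1] & tab$to == avail$to[1], ]
  out <- data.frame(window = sel$window, label = sel$state,
                    condition = sel$condition, start_s = sel$start_s)
  for (q in seq_len(nrow(avail))) {
    v <- tab[tab$from == avail$from[q] & tab$to == avail$to[q], ]
    stopifnot(identical(v$window, out$window))
    out[[paste(avail$from[q], avail$to[q], sep = ".")]] <- v[[value_col]]
  }
  feat_cols <- paste(avail$from, avail$to, sep = ".")
  out <- out[stats::complete.cases(out[, feat_cols, drop = FALSE]), , drop = FALSE]
  for (cls in c("awake", "anesthetized")) {
    if (!any(out$label == cls)) stop("no admitted windows in class '", cls, "'")
  }
  attr(out, "feature_cols") <- feat_cols
  out
}

#' Train/test split for one bootstrap repetition
#'
#' `N_train = min(floor(0.8 N_aw), floor(0.8 N_an), train_cap)` windows are
#' drawn uniformly without replacement from each class for training; all
#' remaining windows of each class form its test set. Repetition `r` under
#' seed `s` always yields the same split.
#'
#' @param n_awake,n_anesth class sizes (each >= 5).
#' @param train_fraction training fraction before capping (default 0.8).
#' @param train_cap ceiling on N_train (default 100).
#' @param seed global seed.
#' @param repetition repetition index (>= 1).
#' @return list with `train_awake`, `train_anesth`, `test_awake`,
#'   `test_anesth` (indices within each class) and `n_train`.
#' @export
bootstrap_split <- function(n_awake, n_anesth, train_fraction = 0.8,
                            train_cap = 100, seed = 1, repetition = 1) {
  stopifnot(n_awake >= 5, n_anesth >= 5, train_fraction > 0, train_fraction < 1,
            train_cap >= 1)
  n_train <- min(floor(train_fraction * n_awake), floor(train_fraction * n_anesth),
                 train_cap)
  if (n_train == 0) stop("N_train is zero; not enough windows per class")
  with_seed(substream_seed(seed, paste0("rep", repetition)), {
    tr_aw <- sort(sample.int(n_awake, n_train))
    tr_an <- sort(sample.int(n_anesth, n_train))
    list(train_awake = tr_aw, train_anesth = tr_an,
         test_awake = setdiff(seq_len(n_awake), tr_aw),
         test_anesth = setdiff(seq_len(n_anesth), tr_an),
         n_train = n_train)
  })
}

standardize_train_test <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sc <- apply(train_x, 2, stats::sd)
  sc[sc == 0] <- 1
  list(train = sweep(sweep(train_x, 2, mu), 2, sc, "/"),
       test = sweep(sweep(test_x, 2, mu), 2, sc, "/"))
}

fisher_lda <- function(train_x, train_y, test_x, ridge = 1e-6) {
  cls <- c("awake", "anesthetized")
  m1 <- colMeans(train_x[train_y == cls[1], , drop = FALSE])
  m0 <- colMeans(train_x[train_y == cls[2], , drop = FALSE])
  n1 <- sum(train_y == cls[1]); n0 <- sum(train_y == cls[2])
  S1 <- stats::cov(train_x[train_y == cls[1], , drop = FALSE])
  S0 <- stats::cov(train_x[train_y == cls[2], , drop = FALSE])
  Sp <- ((n1 - 1) * S1 + (n0 - 1) * S0) / (n1 + n0 - 2)
  w <- tryCatch(solve(Sp, m1 - m0), error = function(e) {
    message("singular pooled covariance; ridge-regularizing LDA (1e-6 load)")
    solve(Sp + diag(ridge, ncol(Sp)), m1 - m0)
  })
  thresh <- sum(w * (m1 + m0)) / 2  # equal priors
  score <- as.matrix(test_x) %*% w
  factor(ifelse(score > thresh, cls[1], cls[2]), levels = cls)
}

#' Train a classifier and predict test labels
#'
#' `LDA` is the Fisher discriminant with pooled within-class covariance and
#' equal priors (ridge-regularized with a fixed 1e-6 diagonal load if the
#' pooled covariance is singular). `SVM_L` and `SVM_NL` are soft-margin
#' support vector machines (cost `C`) with linear and radial-basis kernels;
#' the RBF kernel is `exp(-||u - v||^2 / (2 sigma^2))` with `sigma = 1` on
#' features standardized by the training-set mean and scale, which makes the
#' unit kernel radius comparable across recordings despite inter-subject GC
#' scale differences.
#'
#' @param train data frame of training features.
#' @param train_labels factor/character labels (`awake` / `anesthetized`);
#'   both classes must be present.
#' @param test data frame of test features (same columns).
#' @param method `"LDA"`, `"SVM_L"` or `"SVM_NL"`.
#' @param cost SVM regularization constant (default 1).
#' @param sigma RBF kernel width on standardized features (default 1).
#' @return factor of predicted labels, one per test row.
#' @export
train_and_classify <- function(train, train_labels, test,
                               method = c("LDA", "SVM_L", "SVM_NL"),
                               cost = 1, sigma = 1) {
  method <- match.arg(method)
  train_labels <- as.character(train_labels)
  if (length(unique(train_labels)) < 2)
    stop("training data must contain both classes")
  train_x <- as.matrix(train); test_x <- as.matrix(test)
  if (method == "LDA") return(fisher_lda(train_x, train_labels, test_x))
  std <- standardize_train_test(train_x, test_x)
  y <- factor(train_labels, levels = c("awake", "anesthetized"))
  fit <- if (method == "SVM_L") {
    e1071::svm(std$train, y, kernel = "linear", cost = cost, scale = FALSE)
  } else {
    e1071::svm(std$train, y, kernel = "radial", gamma = 1 / (2 * sigma^2),
               cost = cost, scale = FALSE)
  }
  stats::predict(fit, std$test)
}

#' Specificity, sensitivity and average accuracy of predictions
#'
#' Awake is the positive class: `SE = TruP / TotP`, `SP = TruN / TotN`,
#' `Acc = (SE + SP) / 2`. A class absent from the truth leaves its ratio
#' (and the average) undefined (`NA`).
#'
#' @param predictions,truth equal-length label vectors
#'   (`awake` / `anesthetized`).
#' @return list with `sensitivity`, `specificity`, `average_accuracy` and
#'   the counts `TotP`, `TotN`, `TruP`, `TruN`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  predictions <- as.character(predictions); truth <- as.character(truth)
  stopifnot(length(predictions) == length(truth))
  bad <- setdiff(unique(c(predictions, truth)), c("awake", "anesthetized"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  tot_p <- sum(truth == "awake"); tot_n <- sum(truth == "anesthetized")
  tru_p <- sum(truth == "awake" & predictions == "awake")
  tru_n <- sum(truth == "anesthetized" & predictions == "anesthetized")
  se <- if (tot_p > 0) tru_p / tot_p else NA_real_
  sp <- if (tot_n > 0) tru_n / tot_n else NA_real_
  list(sensitivity = se, specificity = sp,
       average_accuracy = (se + sp) / 2,
       TotP = tot_p, TotN = tot_n, TruP = tru_p, TruN = tru_n)
}

#' One-way ANOVA F-test between two performance samples
#'
#' Used for classifier-vs-classifier and condition-vs-condition comparisons
#' of per-repetition metrics. If both groups have zero within-group variance
#' the convention is `F = 0, p = 1` for equal means and `F = Inf, p = 0`
#' otherwise.
#'
#' @param perf_a,perf_b numeric vectors of per-repetition values.
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `p`, `df`, `significant`.
#' @export
compare_performance <- function(perf_a, perf_b, alpha = 0.05) {
  stopifnot(length(perf_a) >= 1, length(perf_b) >= 1)
  na <- length(perf_a); nb <- length(perf_b)
  gm <- mean(c(perf_a, perf_b))
  ssb <- na * (mean(perf_a) - gm)^2 + nb * (mean(perf_b) - gm)^2
  ssw <- sum((perf_a - mean(perf_a))^2) + sum((perf_b - mean(perf_b))^2)
  df1 <- 1L; df2 <- na + nb - 2L
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df = c(df1, df2), significant = FALSE))
    return(list(F = Inf, p = 0, df = c(df1, df2), significant = TRUE))
  }
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, p = p, df = c(df1, df2), significant = p < alpha)
}

#' Bootstrap classification study over one condition
#'
#' Runs `B` repetitions of split / train / evaluate for each classifier and
#' aggregates the per-repetition specificity, sensitivity and average
#' accuracy as mean and standard deviation.
#'
#' @param features output of [build_features()], restricted by the caller to
#'   one condition if desired.
#' @param B repetitions (default 200).
#' @param methods classifiers to run.
#' @param train_fraction,train_cap see [bootstrap_split()].
#' @param seed global seed.
#' @param cost,sigma SVM hyperparameters.
#' @return object of class `bootstrap_report`: `$per_repetition` (long data
#'   frame: repetition, method, sensitivity, specificity, average_accuracy),
#'   `$summary` (mean and sd per method and metric), `$n_train`, `$counts`.
#' @export
bootstrap_study <- function(features, B = 200,
                            methods = c("LDA", "SVM_L", "SVM_NL"),
                            train_fraction = 0.8, train_cap = 100,
                            seed = 1, cost = 1, sigma = 1) {
  stopifnot(B >= 1)
  feat_cols <- attr(features, "feature_cols") %||%
    intersect(c("LF.LP", "RF.LP", "LF.RP", "RF.RP"), colnames(features))
  X <- features[, feat_cols, drop = FALSE]
  lab <- features$label
  iaw <- which(lab == "awake"); ian <- which(lab == "anesthetized")
  rows <- vector("list", B * length(methods))
  ri <- 0L
  n_train <- NA_integer_
  for (b in seq_len(B)) {
    sp <- bootstrap_split(length(iaw), length(ian), train_fraction, train_cap,
                          seed = seed, repetition = b)
    n_train <- sp$n_train
    tr_idx <- c(iaw[sp$train_awake], ian[sp$train_anesth])
    te_idx <- c(iaw[sp$test_awake], ian[sp$test_anesth])
    for (m in methods) {
      pred <- train_and_classify(X[tr_idx, , drop = FALSE], lab[tr_idx],
                                 X[te_idx, , drop = FALSE], m,
                                 cost = cost, sigma = sigma)
      ev <- evaluate_predictions(pred, lab[te_idx])
      ri <- ri + 1L
      rows[[ri]] <- data.frame(repetition = b, method = m,
                               sensitivity = ev$sensitivity,
                               specificity = ev$specificity,
                               average_accuracy = ev$average_accuracy)
    }
  }
  per_rep <- do.call(rbind, rows)
  metrics <- c("sensitivity", "specificity", "average_accuracy")
  summ <- do.call(rbind, lapply(methods, function(m) {
    sub <- per_rep[per_rep$method == m, ]
    data.frame(method = m, metric = metrics,
               mean = vapply(metrics, function(k) mean(sub[[k]]), 0),
               sd = vapply(metrics, function(k) stats::sd(sub[[k]]), 0))
  }))
  rownames(summ) <- NULL
  structure(list(per_repetition = per_rep, summary = summ, n_train = n_train,
                 counts = c(awake = length(iaw), anesthetized = length(ian)),
                 B = B),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("Bootstrap study: B = %d, N_train = %d (awake %d, anesthetized %d)\n",
              x$B, x$n_train, x$counts["awake"], x$counts["anesthetized"]))
  s <- x$summary
  for (m in unique(s$method)) {
    sub <- s[s$method == m, ]
    cat(sprintf("  %-6s SP %.3f+-%.3f  SE %.3f+-%.3f  Acc %.3f+-%.3f\n", m,
                sub$mean[sub$metric == "specificity"], sub$sd[sub$metric == "specificity"],
                sub$mean[sub$metric == "sensitivity"], sub$sd[sub$metric == "sensitivity"],
                sub$mean[sub$metric == "average_accuracy"], sub$sd[sub$metric == "average_accuracy"]))
  }
  invisible(x)
}
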