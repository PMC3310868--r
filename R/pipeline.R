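## End-to-end pipeline: ingest -> AR gating -> GC -> surrogates -> bootstrap
## classification, with structured attrition logging and a single global seed
## from which every stochastic stage derives its substream.

#' Pipeline configuration
#'
#' Either `input` (a recording file readable by [read_recording()]) or `sim`
#' (a [sim_config()]) must be supplied. Defaults mirror the analysis
#' conventions used throughout the package: 4-s windows sliding by 1 s, a
#' 5-minute post-induction exclusion, fixed AR order 6, trailing
#' moving-average smoothing over 10 windows, 19 phase-randomized surrogates,
#' and a 200-repetition bootstrap with an 80% / 100-window training rule.
#'
#' @param input optional path to a recording file.
#' @param sim optional `sim_config` for synthetic input.
#' @param ar_order fixed integer order, or `"bic"` to select the order by
#'   BIC over a sample of windows.
#' @param p_max order bound for BIC selection (default 12).
#' @param window_s,step_s window geometry in seconds (4, 1).
#' @param post_induction_skip seconds discarded after LOC (300).
#' @param n_anesth_windows anesthetized-window cap per condition (300).
#' @param smoothing moving-average length in windows (10).
#' @param notch_50hz apply the optional 50-Hz notch before analysis (off by
#'   default: the reference pipeline is unfiltered).
#' @param pairs `"all"` or `"frontal_posterior"` (restrict GC to the feature
#'   pairs; faster, identical classification results).
#' @param n_surrogates phase-randomized surrogates per tested window (19).
#' @param n_significance_windows number of admitted windows per condition on
#'   which surrogate significance thresholds are computed (20; thresholds
#'   are diagnostics, not classification inputs, so a sample suffices).
#' @param volume_conduction run the source-shift volume-conduction control.
#' @param vc_shift source shift T in samples (100).
#' @param B bootstrap repetitions (200).
#' @param train_fraction,train_cap training-set rule (0.8, 100).
#' @param svm_cost,svm_sigma SVM hyperparameters (1, 1).
#' @param kpss_level KPSS critical level (0.01).
#' @param consistency_min consistency admission threshold in percent (70).
#' @param output_dir optional directory for reports.
#' @param seed global seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, ar_order = 6, p_max = 12,
                            window_s = 4, step_s = 1,
                            post_induction_skip = 300, n_anesth_windows = 300,
                            smoothing = 10, notch_50hz = FALSE,
                            pairs = c("all", "frontal_posterior"),
                            n_surrogates = 19, n_significance_windows = 20,
                            volume_conduction = TRUE, vc_shift = 100,
                            B = 200, train_fraction = 0.8, train_cap = 100,
                            svm_cost = 1, svm_sigma = 1,
                            kpss_level = 0.01, consistency_min = 70,
                            output_dir = NULL, seed = 1) {
  pairs <- match.arg(pairs)
  if (is.null(input) && is.null(sim))
    stop("config invalid: supply either an input path or a sim_config")
  if (!is.null(input) && !file.exists(input))
    stop("config invalid: input file does not exist: ", input)
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    stop("config invalid: sim must be a sim_config")
  if (!identical(ar_order, "bic")) {
    ar_order <- as.integer(ar_order)
    if (is.na(ar_order) || ar_order < 1) stop("ar_order must be >= 1 or 'bic'")
  }
  for (v in c(window_s, step_s, smoothing, n_surrogates, B, train_fraction,
              train_cap, svm_cost, svm_sigma, consistency_min, p_max))
    if (!is.numeric(v) || v <= 0) stop("config invalid: all numeric fields must be positive")
  if (post_induction_skip < 0 || n_anesth_windows < 1 ||
      n_significance_windows < 0 || vc_shift < 0)
    stop("config invalid: negative field")
  structure(as.list(environment()), class = "pipeline_config")
}

log_line <- function(log, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  c(log, jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA))
}

#' Run the full pipeline
#'
#' Executes ingest (read or simulate, bad-channel exclusion, region
#' averaging, optional notch), window extraction with the four QC gates, GC
#' estimation and smoothing, phase-randomized significance thresholds on a
#' window sample, the source-shift volume-conduction control, feature
#' building and the bootstrap classification study per condition, plus the
#' classifier-vs-classifier and LOC-vs-ROC ANOVA comparisons. Per-stage
#' window attrition is logged as line-delimited JSON.
#'
#' @param cfg a [pipeline_config()].
#' @return an object of class `pipeline_result` with elements `recording`,
#'   `windows`, `gc`, `significance`, `volume_conduction`, `features`,
#'   `bootstrap` (per condition), `comparisons`, `attrition`, `log`, `cfg`.
#'   If `cfg$output_dir` is set, reports are also written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- character(0)

  rec <- if (!is.null(cfg$input)) read_recording(cfg$input)
         else generate_recording(cfg$sim)
  log <- log_line(log, "ingest", channels = nrow(rec$signal),
                  samples = ncol(rec$signal), fs = rec$fs)

  bad <- detect_bad_channels(rec)
  log <- log_line(log, "bad_channels", excluded = I(bad))
  rs <- average_regions(rec, excluded = bad)
  if (cfg$notch_50hz) rs <- notch_50hz(rs)

  ws <- extract_state_segments(rs, post_induction_skip = cfg$post_induction_skip,
                               n_anesth_windows = cfg$n_anesth_windows,
                               window_s = cfg$window_s, step_s = cfg$step_s,
                               ar_order = if (identical(cfg$ar_order, "bic")) 6 else cfg$ar_order,
                               kpss_level = cfg$kpss_level,
                               consistency_min = cfg$consistency_min,
                               seed = substream_seed(cfg$seed, "qc"))

  order_used <- cfg$ar_order
  if (identical(cfg$ar_order, "bic")) {
    adm <- which(ws$index$stationary & ws$index$dw_ok & ws$index$artifact_free)
    samp <- with_seed(substream_seed(cfg$seed, "bic"),
                      sample(adm, min(20, length(adm))))
    fp <- feature_pair_regions(ws$regions_present)
    wp <- lapply(samp, function(w) {
      win <- window_data(ws, w)
      cbind(win[, fp$from[1]], win[, fp$to[1]])
    })
    order_used <- select_order_bic(wp, p_max = cfg$p_max)
    log <- log_line(log, "order_selection", method = "bic", order = order_used)
  }

  gcs <- regionwise_gc(ws, p = order_used, pairs = cfg$pairs)
  gcs <- smooth_gc_series(gcs, n = cfg$smoothing)
  log <- log_line(log, "gc", as.list(gcs$attrition))

  significance <- NULL
  if (cfg$n_significance_windows > 0) {
    adm <- which(ws$index$stationary & ws$index$dw_ok & ws$index$consistent &
                   ws$index$artifact_free)
    sig_rows <- list()
    fp <- feature_pair_regions(ws$regions_present)
    for (cond in unique(ws$index$condition[adm])) {
      cand <- adm[ws$index$condition[adm] == cond]
      take <- utils::head(cand, cfg$n_significance_windows)
      for (w in take) {
        win <- window_data(ws, w)
        for (q in seq_len(nrow(fp))) {
          th <- gc_significance_threshold(win[, fp$from[q]], win[, fp$to[q]],
                                          p = if (identical(order_used, "bic")) 6 else order_used,
                                          n_surrogates = cfg$n_surrogates,
                                          seed = substream_seed(cfg$seed, paste0("sig", w, "_", q)))
          sig_rows[[length(sig_rows) + 1]] <- data.frame(
            condition = cond, window = w, state = ws$index$state[w],
            from = fp$from[q], to = fp$to[q],
            gc = th$gc$gc_12, threshold = th$threshold_12,
            significant = th$significant_12)
        }
      }
    }
    significance <- do.call(rbind, sig_rows)
    log <- log_line(log, "significance", windows_tested = length(unique(significance$window)),
                    significant_fraction = mean(significance$significant))
  }

  vc <- NULL
  if (isTRUE(cfg$volume_conduction)) {
    vc <- tryCatch(
      volume_conduction_report(rec, shift = cfg$vc_shift,
                               p = if (identical(order_used, "bic")) 6 else order_used,
                               post_induction_skip = cfg$post_induction_skip,
                               n_anesth_windows = cfg$n_anesth_windows,
                               window_s = cfg$window_s, step_s = cfg$step_s),
      error = function(e) { structure(list(error = conditionMessage(e)), class = "vc_failed") })
    if (!inherits(vc, "vc_failed"))
      log <- log_line(log, "volume_conduction", r2_pairwise = vc$pairwise$r2,
                      r2_pooled = vc$pooled$r2, verdict = vc$pairwise$verdict)
    else log <- log_line(log, "volume_conduction", error = vc$error)
  }

  features <- build_features(gcs)
  boots <- list()
  for (cond in intersect(c("LOC", "ROC"), unique(features$condition))) {
    sub <- features[features$condition == cond, , drop = FALSE]
    attr(sub, "feature_cols") <- attr(features, "feature_cols")
    cls_n <- table(factor(sub$label, c("awake", "anesthetized")))
    if (any(cls_n < 5)) {
      log <- log_line(log, "bootstrap", condition = cond, skipped = TRUE,
                      reason = "fewer than 5 windows in a class",
                      counts = as.list(cls_n))
      next
    }
    boots[[cond]] <- bootstrap_study(sub, B = cfg$B,
                                     train_fraction = cfg$train_fraction,
                                     train_cap = cfg$train_cap,
                                     seed = substream_seed(cfg$seed, paste0("boot", cond)),
                                     cost = cfg$svm_cost, sigma = cfg$svm_sigma)
    log <- log_line(log, "bootstrap", condition = cond,
                    n_train = boots[[cond]]$n_train,
                    counts = as.list(boots[[cond]]$counts))
  }

  comparisons <- pipeline_comparisons(boots)

  res <- structure(list(recording = rec, windows = ws, gc = gcs,
                        significance = significance, volume_conduction = vc,
                        features = features, bootstrap = boots,
                        comparisons = comparisons,
                        attrition = gcs$attrition, ar_order = order_used,
                        log = log, cfg = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$output_dir)) write_pipeline_reports(res, cfg$output_dir)
  res
}

pipeline_comparisons <- function(boots) {
  out <- list()
  metrics <- c("specificity", "sensitivity", "average_accuracy")
  get <- function(rep, m, k) rep$per_repetition[rep$per_repetition$method == m, k]
  for (cond in names(boots)) {
    rep <- boots[[cond]]
    methods <- unique(rep$per_repetition$method)
    if (length(methods) >= 2) {
      cmb <- utils::combn(methods, 2)
      for (j in seq_len(ncol(cmb))) for (k in metrics) {
        cp <- compare_performance(get(rep, cmb[1, j], k), get(rep, cmb[2, j], k))
        out[[length(out) + 1]] <- data.frame(
          comparison = "classifier", condition = cond,
          a = cmb[1, j], b = cmb[2, j], metric = k,
          F = cp$F, p = cp$p, significant = cp$significant)
      }
    }
  }
  if (all(c("LOC", "ROC") %in% names(boots))) {
    methods <- unique(boots$LOC$per_repetition$method)
    for (m in methods) for (k in metrics) {
      cp <- compare_performance(get(boots$LOC, m, k), get(boots$ROC, m, k))
      out[[length(out) + 1]] <- data.frame(
        comparison = "condition", condition = "LOCvsROC", a = m, b = m,
        metric = k, F = cp$F, p = cp$p, significant = cp$significant)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

write_pipeline_reports <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(format_table_num(res$gc$table), "gc_series.tsv")
  wt(format_table_num(window_table(res$windows)), "windows.tsv")
  summaries <- do.call(rbind, lapply(names(res$bootstrap), function(cond) {
    s <- res$bootstrap[[cond]]$summary
    cbind(condition = cond, s)
  }))
  if (!is.null(summaries)) wt(format_table_num(summaries), "bootstrap_summary.tsv")
  if (!is.null(res$comparisons)) wt(format_table_num(res$comparisons), "comparisons.tsv")
  report <- list(
    ar_order = res$ar_order,
    attrition = as.list(res$attrition),
    bootstrap = lapply(res$bootstrap, function(b)
      list(n_train = b$n_train, counts = as.list(b$counts),
           summary = b$summary)),
    volume_conduction = if (!is.null(res$volume_conduction) &&
                            !inherits(res$volume_conduction, "vc_failed"))
      list(r2_pairwise = res$volume_conduction$pairwise$r2,
           r2_pooled = res$volume_conduction$pooled$r2,
           verdict = res$volume_conduction$pairwise$verdict,
           gc_original = signif(res$volume_conduction$pairwise$x, 12),
           gc_surrogate = signif(res$volume_conduction$pairwise$y, 12)) else NULL,
    significance = if (!is.null(res$significance))
      list(windows_tested = length(unique(res$significance$window)),
           significant_fraction = mean(res$significance$significant)) else NULL)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  writeLines(res$log, file.path(dir, "log.jsonl"))
  invisible(dir)
}

## round floating point columns so report files are byte-stable across
## platforms at equal seeds
format_table_num <- function(tab, digits = 12) {
  for (j in seq_along(tab)) if (is.numeric(tab[[j]])) tab[[j]] <- signif(tab[[j]], digits)
  tab
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n===============\n")
  cat("AR order:", x$ar_order, "\n")
  cat("Attrition:", paste(sprintf("%s=%d", names(x$attrition), x$attrition),
                          collapse = ", "), "\n")
  for (cond in names(x$bootstrap)) {
    cat("\nCondition", cond, "\n")
    print(x$bootstrap[[cond]])
  }
  if (!is.null(x$volume_conduction) && !inherits(x$volume_conduction, "vc_failed")) {
    cat("\n"); print(x$volume_conduction$pairwise)
  }
  invisible(x)
}
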