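#' Stratified train/test split of a manifest
#'
#' Disjoint, exhaustive partition with the test side sized
#' `floor((1 - ratio) * N)` and stratified by device and class: per-stratum
#' test counts follow the largest-remainder rule so they sum exactly to the
#' target. Deterministic under `seed`.
#'
#' @param manifest Manifest `data.frame` with `device` and `label` columns.
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` manifest subsets.
#' @export
split_train_test <- function(manifest, ratio, seed = 1) {
  stopifnot(ratio > 0, ratio < 1)
  N <- nrow(manifest)
  test_n <- floor((1 - ratio) * N)
  if (test_n < 1 || test_n >= N)
    stop("split would leave an empty train or test side")
  strata <- interaction(manifest$device, manifest$label, drop = TRUE)
  levs <- levels(strata)
  sizes <- as.integer(table(strata)[levs])
  ideal <- (1 - ratio) * sizes
  base <- pmin(floor(ideal), sizes)
  rem <- test_n - sum(base)
  if (rem > 0) {
    ord <- order(-(ideal - floor(ideal)), seq_along(levs))
    for (k in ord) {
      if (rem == 0) break
      if (base[k] < sizes[k]) { base[k] <- base[k] + 1L; rem <- rem - 1L }
    }
  }
  test_idx <- integer(0)
  for (k in seq_along(levs)) {
    rows <- which(strata == levs[k])
    if (base[k] > 0) {
      pick <- with_seed(derive_seed(seed, paste0("stratum", levs[k])),
                        sample(rows, base[k]))
      test_idx <- c(test_idx, pick)
    }
  }
  list(train = manifest[setdiff(seq_len(N), test_idx), , drop = FALSE],
       test = manifest[sort(test_idx), , drop = FALSE])
}

#' Classification metrics at a threshold
#'
#' Precision, recall, F1, accuracy from the confusion matrix at the given
#' threshold (label 1 = sulfur-fumigated = positive class; scores on the
#' boundary go to the positive class), plus rank-based ROC-AUC with midrank
#' tie handling. Ratios with a zero denominator are reported as 0 and named
#' in the `undefined` field rather than returned as `NaN`, so aggregation
#' over many repeats never drops results silently.
#'
#' @param labels Integer 0/1 vector.
#' @param scores Numeric scores/probabilities of the same length.
#' @param threshold Decision threshold.
#' @return A `metrics_report`: list with `precision`, `recall`, `f1`,
#'   `auc_roc`, `accuracy`, `confusion` (tp/fp/tn/fn), `n_test`,
#'   `undefined` (character vector of flagged metrics).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  n <- length(labels)
  stopifnot(n >= 1, length(scores) == n, all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  undefined <- character(0)
  ratio0 <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); 0 } else num / den
  }
  precision <- ratio0(tp, tp + fp, "precision")
  recall <- ratio0(tp, tp + fn, "recall")
  f1 <- ratio0(2 * precision * recall, precision + recall, "f1")
  accuracy <- (tp + tn) / n
  npos <- sum(labels == 1); nneg <- n - npos
  if (npos == 0 || nneg == 0) {
    auc <- 0
    undefined <- c(undefined, "auc_roc")
  } else {
    r <- rank(scores)  # midranks for ties
    auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 auc_roc = auc, accuracy = accuracy,
                 confusion = list(tp = tp, fp = fp, tn = tn, fn = fn),
                 n_test = n, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d | precision %.4f  recall %.4f  F1 %.4f  AUC-ROC %.4f  accuracy %.4f\n",
    x$n_test, x$precision, x$recall, x$f1, x$auc_roc, x$accuracy))
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn, x$confusion$fn))
  if (length(x$undefined))
    cat("undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a model on a labelled image set
#'
#' @param model Model with a transform configuration.
#' @param data List with `x` (images or feature matrix) and `y` labels.
#' @param threshold Decision threshold.
#' @param batch_size Evaluation batch size.
#' @return A [compute_metrics()] report with the scores attached as
#'   attribute `"scores"`.
#' @export
evaluate_model <- function(model, data, threshold = 0.5, batch_size = 32) {
  n <- validate_dataset(data)
  scores <- numeric(n)
  for (i in seq(1, n, by = batch_size)) {
    j <- min(i + batch_size - 1, n)
    b <- prepare_batch(model, data, i:j, train = FALSE)
    scores[i:j] <- model_scores(model, b$x)
  }
  rep <- compute_metrics(data$y, scores, threshold)
  attr(rep, "scores") <- scores
  rep
}

#' Aggregate metric reports over repeats
#'
#' Averaging per-repeat metrics (mean of metrics) and recomputing the
#' threshold metrics from the pooled confusion counts (metric of means)
#' give different numbers whenever repeats are imbalanced; both are
#' reported, clearly labelled. The pooled AUC is the mean of per-repeat
#' AUCs (ranks do not pool across repeats).
#'
#' @param reports List of [compute_metrics()] reports.
#' @return List with `mean_of_metrics` and `pooled` (metric-of-means).
#' @export
summarize_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  fields <- c("precision", "recall", "f1", "auc_roc", "accuracy")
  mom <- vapply(fields, function(f)
    mean(vapply(reports, `[[`, 0, f)), 0)
  cf <- Reduce(function(a, b) Map(`+`, a, b),
               lapply(reports, `[[`, "confusion"))
  pre <- if (cf$tp + cf$fp == 0) 0 else cf$tp / (cf$tp + cf$fp)
  rec <- if (cf$tp + cf$fn == 0) 0 else cf$tp / (cf$tp + cf$fn)
  pooled <- list(
    precision = pre, recall = rec,
    f1 = if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec),
    auc_roc = mom[["auc_roc"]],
    accuracy = (cf$tp + cf$tn) / (cf$tp + cf$fp + cf$tn + cf$fn),
    confusion = cf)
  list(mean_of_metrics = as.list(mom), pooled = pooled)
}

#' Repeated random-split experiment
#'
#' For each repeat: a fresh stratified split at `ratio` (independent
#' derived seed), a full training run per the pipeline configuration, and
#' an evaluation on the held-out test side. Train and test never overlap
#' within a repeat.
#'
#' @param manifest Manifest `data.frame`.
#' @param images Named list of images keyed by `sample_id` (see
#'   [load_images()]), or a feature matrix with columns named by
#'   `sample_id`.
#' @param ratio Training fraction.
#' @param repeats Number of repeats (`>= 1`).
#' @param config Pipeline configuration, see [pipeline_config()].
#' @param seed Integer seed.
#' @return List of [compute_metrics()] reports, one per repeat.
#' @export
repeated_split_experiment <- function(manifest, images, ratio, repeats,
                                      config, seed = 1) {
  stopifnot(repeats >= 1)
  lapply(seq_len(repeats), function(r) {
    rs <- derive_seed(seed, sprintf("rep%d", r))
    sp <- split_train_test(manifest, ratio, seed = rs)
    train_and_evaluate(sp$train, sp$test, images, config, seed = rs)
  })
}

#' Training-ratio sensitivity sweep
#'
#' Repeats the repeated-split experiment at each training ratio and
#' summarizes the accuracy distribution per ratio (mean, median, quartiles,
#' whiskers) for boxplot-style stability analysis. Repeat `r` uses the same
#' derived seed at every ratio, so the splits are coupled across ratios
#' (the per-stratum draws nest as the ratio changes) and ratio-to-ratio
#' comparisons are paired — a common-random-numbers design that sharpens
#' the trend estimate at a fixed repeat count.
#'
#' @inheritParams repeated_split_experiment
#' @param ratios Vector of training fractions in (0, 1).
#' @return A `sweep_result_list`: per ratio, a `sweep_result` with the
#'   per-repeat accuracies and their summary.
#' @export
ratio_sweep <- function(manifest, images, ratios, repeats, config, seed = 1) {
  stopifnot(all(ratios > 0), all(ratios < 1))
  out <- lapply(ratios, function(rt) {
    reports <- repeated_split_experiment(
      manifest, images, rt, repeats, config, seed = seed)
    acc <- vapply(reports, `[[`, 0, "accuracy")
    q <- stats::quantile(acc, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    structure(list(ratio = rt, repeats = repeats, accuracies = acc,
                   mean = mean(acc), median = q[2], q1 = q[1], q3 = q[3],
                   whisker_low = min(acc[acc >= q[1] - 1.5 * iqr]),
                   whisker_high = max(acc[acc <= q[3] + 1.5 * iqr]),
                   reports = reports),
              class = "sweep_result")
  })
  structure(out, class = "sweep_result_list")
}

#' @export
print.sweep_result_list <- function(x, ...) {
  cat("training-ratio sweep\n")
  for (s in x)
    cat(sprintf("  ratio %.2f: mean acc %.4f  median %.4f  IQR [%.4f, %.4f]  (n = %d)\n",
                s$ratio, s$mean, s$median, s$q1, s$q3, s$repeats))
  invisible(x)
}

#' @export
plot.sweep_result_list <- function(x, ...) {
  graphics::boxplot(lapply(x, `[[`, "accuracies"),
                    names = sprintf("%.1f", vapply(x, `[[`, 0, "ratio")),
                    xlab = "training set ratio", ylab = "accuracy", ...)
  invisible(x)
}
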