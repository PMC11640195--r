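fake_manifest <- function(devices = c("iPh", "Vo", "Ho", "Mi"),
                          hs = 66, ns = 68) {
  do.call(rbind, lapply(devices, function(d) {
    data.frame(sample_id = sprintf("%s_%s_%02d", d,
                                   rep(c("HS", "NS"), c(hs, ns)),
                                   c(seq_len(hs), seq_len(ns))),
               path = "x.png", device = d,
               label = rep(c(1L, 0L), c(hs, ns)),
               width = 10L, height = 10L, stringsAsFactors = FALSE)
  }))
}

test_that("splits are disjoint, exhaustive and sized by the floor rule", {
  man <- fake_manifest()  # 536 rows
  sp <- split_train_test(man, 0.8, seed = 1)
  expect_equal(nrow(sp$test), 107)  # floor(0.2 * 536)
  expect_equal(nrow(sp$train), 429)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), man$sample_id)
  # stratification: every device contributes 26-27 test rows
  expect_true(all(table(sp$test$device) %in% 26:27))
  # both classes present on both sides
  expect_true(all(table(sp$test$label) > 0))
  expect_error(split_train_test(man[1:3, ], 0.9), "empty")
})

test_that("different seeds give different partitions", {
  man <- fake_manifest(devices = "A", hs = 20, ns = 20)
  same <- vapply(1:20, function(i) {
    a <- split_train_test(man, 0.5, seed = i)$test$sample_id
    b <- split_train_test(man, 0.5, seed = i + 1000)$test$sample_id
    setequal(a, b)
  }, TRUE)
  expect_lt(mean(same), 0.2)
  # and the same seed reproduces the same partition
  expect_identical(split_train_test(man, 0.5, seed = 4),
                   split_train_test(man, 0.5, seed = 4))
})

test_that("threshold metrics match brute-force definitions exhaustively", {
  # realize every confusion matrix with entries <= 5 as label/score vectors
  for (tp in 0:5) for (fp in 0:5) for (tn in 0:5) for (fn in 0:5) {
    n <- tp + fp + tn + fn
    if (n == 0) next
    labels <- rep(c(1, 0, 0, 1), c(tp, fp, tn, fn))
    scores <- rep(c(0.9, 0.9, 0.1, 0.1), c(tp, fp, tn, fn))
    r <- suppressWarnings(compute_metrics(labels, scores, 0.5))
    expect_equal(unlist(r$confusion), c(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(r$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
    expect_equal(r$recall, if (tp + fn == 0) 0 else tp / (tp + fn))
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
    expect_equal(r$f1, if (p + rc == 0) 0 else 2 * p * rc / (p + rc))
    expect_equal(r$accuracy, (tp + tn) / n)
  }
})

test_that("the printed all-correct confusion matrix gives accuracy 1", {
  labels <- rep(c(1, 0), c(57, 50))
  scores <- rep(c(0.95, 0.05), c(57, 50))
  r <- compute_metrics(labels, scores)
  expect_equal(unlist(r$confusion), c(tp = 57, fp = 0, tn = 50, fn = 0))
  expect_equal(r$accuracy, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)  # harmonic mean of two ones
  expect_equal(r$auc_roc, 1)
})

test_that("rank-based AUC equals exhaustive pair counting", {
  pair_auc <- function(labels, scores) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    s <- 0
    for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  # perfect separation and full ties
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc_roc, 1)
  expect_equal(compute_metrics(c(1, 0, 1, 0), rep(0.5, 4))$auc_roc, 0.5)
  set.seed(19)
  for (rep in 1:4) {
    n <- 200
    labels <- rbinom(n, 1, 0.45)
    if (sum(labels) %in% c(0, n)) next
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(compute_metrics(labels, scores)$auc_roc,
                 pair_auc(labels, scores), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  labels <- rbinom(120, 1, 0.5)
  scores <- runif(120) + 0.4 * labels
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(compute_metrics(labels, scores)$auc_roc, ref,
               tolerance = 1e-10)
})

test_that("degenerate inputs are flagged, not fabricated", {
  r <- compute_metrics(c(1, 1), c(0.2, 0.3))
  expect_true("auc_roc" %in% r$undefined)
  expect_equal(r$auc_roc, 0)
  r2 <- compute_metrics(c(0, 0, 1), c(0.1, 0.2, 0.3), threshold = 0.9)
  expect_true("precision" %in% r2$undefined)  # nothing predicted positive
  expect_equal(r2$precision, 0)
})

test_that("reports are invariant under joint permutation", {
  set.seed(31)
  labels <- rbinom(50, 1, 0.5)
  scores <- runif(50)
  perm <- sample(50)
  a <- compute_metrics(labels, scores)
  b <- compute_metrics(labels[perm], scores[perm])
  for (f in c("precision", "recall", "f1", "auc_roc", "accuracy"))
    expect_equal(a[[f]], b[[f]])
})

test_that("aggregation reports both mean-of-metrics and pooled metrics", {
  r1 <- compute_metrics(c(1, 0), c(0.9, 0.1))          # perfect, n = 2
  r2 <- compute_metrics(rep(c(1, 0), c(4, 4)),
                        c(0.9, 0.2, 0.2, 0.2, 0.1, 0.1, 0.1, 0.9))
  s <- summarize_reports(list(r1, r2))
  expect_equal(s$mean_of_metrics$accuracy,
               mean(c(r1$accuracy, r2$accuracy)))
  cf <- Map(`+`, r1$confusion, r2$confusion)
  expect_equal(s$pooled$accuracy, (cf$tp + cf$tn) / 10)
  expect_equal(s$pooled$precision, cf$tp / (cf$tp + cf$fp))
  # the two aggregates genuinely differ on imbalanced repeats
  expect_false(isTRUE(all.equal(s$mean_of_metrics$accuracy,
                                s$pooled$accuracy)))
})

test_that("repeated splits compose a single run per repeat", {
  man <- fake_manifest(devices = "A", hs = 16, ns = 16)
  feats <- sapply(man$sample_id, function(id)
    rnorm(6) + 1.5 * (2 * man$label[man$sample_id == id] - 1))
  set.seed(2)
  cfg <- pipeline_config(mode = "plain",
                         train = train_config(inner_lr = 0.05, seed = 1,
                                              inner_steps = 5,
                                              batch_size = 8),
                         model_builder = function(seed)
                           linear_classifier(6, seed))
  reps <- repeated_split_experiment(man, feats, 0.5, 3, cfg, seed = 11)
  expect_length(reps, 3)
  # repeats = 1 equals a manual run with the same derived seed
  one <- repeated_split_experiment(man, feats, 0.5, 1, cfg, seed = 11)
  rs <- derive_seed(11, "rep1")
  sp <- split_train_test(man, 0.5, seed = rs)
  manual <- train_and_evaluate(sp$train, sp$test, feats, cfg, seed = rs)
  expect_equal(one[[1]]$accuracy, manual$accuracy)
  expect_equal(attr(one[[1]], "scores"), attr(manual, "scores"))
})

test_that("the ratio sweep summarizes accuracy distributions correctly", {
  man <- fake_manifest(devices = "A", hs = 16, ns = 16)
  set.seed(5)
  feats <- sapply(seq_len(nrow(man)), function(i)
    rnorm(4) + 2 * (2 * man$label[i] - 1))
  colnames(feats) <- man$sample_id
  cfg <- pipeline_config(mode = "plain",
                         train = train_config(inner_lr = 0.05, seed = 1,
                                              inner_steps = 5, batch_size = 8),
                         model_builder = function(seed)
                           linear_classifier(4, seed))
  sw <- ratio_sweep(man, feats, ratios = 0.5, repeats = 3, cfg, seed = 7)
  expect_length(sw, 1)
  s <- sw[[1]]
  expect_length(s$accuracies, 3)
  # summaries match an independent sort-based quantile computation
  expect_equal(s$median, quantile(s$accuracies, 0.5, names = FALSE))
  expect_equal(s$q1, quantile(s$accuracies, 0.25, names = FALSE))
  expect_equal(s$q3, quantile(s$accuracies, 0.75, names = FALSE))
  expect_equal(s$mean, mean(s$accuracies))
  expect_true(s$q1 <= s$median && s$median <= s$q3)
})
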