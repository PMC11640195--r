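# Most behavioural checks run on the fast linear model, which implements the
# same model interface as the hybrid network.

sep_features <- function(n, d = 8, shift = 2, seed = 1) {
  # two Gaussian classes separated along every coordinate
  with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    x <- matrix(rnorm(d * n), d) + matrix(shift * (2 * y - 1), d, n,
                                          byrow = TRUE)
    list(x = x, y = y)
  })
}

test_that("the mean squared error loss matches hand arithmetic", {
  expect_equal(mse_loss(c(0.3, 0.8), c(0.3, 0.8)), 0)
  expect_equal(mse_loss(0.75, 1), 0.0625)
  expect_equal(mse_loss(c(0.2, 0.9), c(0, 1)), 0.025)
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
  expect_error(mse_loss(c(0.1, 0.2), 1), "length")
})

test_that("moment updates follow the printed recursions exactly", {
  st <- moment_state(list(a = 0))
  expect_equal(st$o, 0L)
  s1 <- moment_update(st, list(a = 1))
  expect_equal(s1$m$a, 0.1)
  expect_equal(s1$v$a, 0.001)
  expect_equal(s1$o, 1L)
  # zero gradient leaves fresh moments at zero
  s0 <- moment_update(st, list(a = 0))
  expect_equal(s0$m$a, 0)
  expect_equal(s0$v$a, 0)
  # geometric-series limit: repeated constant gradient converges to (c, c^2).
  # The first moment (decay 0.9) converges within ~150 steps; the second
  # (decay 0.999) needs ~20000 steps to reach the same tolerance.
  s <- moment_state(list(a = 0))
  for (i in 1:20000) s <- moment_update(s, list(a = 3))
  expect_equal(s$m$a, 3, tolerance = 1e-6)
  expect_equal(s$v$a, 9, tolerance = 1e-6)
  expect_error(moment_update(st, list(b = 1)), "shape")
})

test_that("moments agree with an independent scalar oracle to 1e-10", {
  set.seed(7)
  for (rep in 1:5) {
    grads <- rnorm(100)
    orc <- oracle_moments(grads)
    st <- moment_state(list(th = 0))
    for (i in seq_along(grads)) {
      st <- moment_update(st, list(th = grads[i]))
      expect_equal(st$m$th, orc$m[i], tolerance = 1e-10)
      expect_equal(st$v$th, orc$v[i], tolerance = 1e-10)
    }
  }
})

test_that("both update rules match the scalar oracle", {
  st <- moment_state(list(th = 0))
  st <- moment_update(st, list(th = 1))  # m = 0.1, v = 0.001, o = 1
  p0 <- list(th = 0)
  # raw stabilized step: 0.01 * 0.1 / (sqrt(0.001) + 1e-8)
  raw <- apply_update(p0, st, 0.01, "adam", correct = FALSE)
  expect_equal(-raw$th, 0.01 * 0.1 / (sqrt(0.001) + 1e-8), tolerance = 1e-12)
  expect_equal(-raw$th, 0.031623, tolerance = 1e-4)
  # printed literal step: 0.01 * 0.1 / (1e-8 + 0.001)
  lit <- apply_update(p0, st, 0.01, "literal")
  expect_equal(-lit$th, 0.01 * 0.1 / (1e-8 + 0.001), tolerance = 1e-12)
  expect_equal(-lit$th, 0.99999, tolerance = 1e-4)
  # bias-corrected step at o = 1: mhat = vhat = 1
  bc <- apply_update(p0, st, 0.01, "adam")
  expect_equal(-bc$th, 0.01 * 1 / (1 + 1e-8), tolerance = 1e-12)
  # zero first moment leaves parameters unchanged
  stz <- moment_state(list(th = 5))
  expect_equal(apply_update(list(th = 5), stz, 0.01, "adam")$th, 5)
  expect_error(apply_update(p0, st, 0), "positive")
})

test_that("update rules match the oracle along whole random trajectories", {
  set.seed(11)
  for (mode in c("adam", "literal")) {
    grads <- rnorm(60)
    orc <- oracle_moments(grads)
    st <- moment_state(list(th = 0))
    th <- 0.5
    th_oracle <- 0.5
    for (i in seq_along(grads)) {
      st <- moment_update(st, list(th = grads[i]))
      th <- apply_update(list(th = th), st, 0.003, mode)$th
      th_oracle <- th_oracle - oracle_step(orc$m[i], orc$v[i], i, 0.003,
                                           mode)
      expect_equal(th, th_oracle, tolerance = 1e-10)
    }
  }
})

test_that("an episode descends a smooth one-parameter objective", {
  # sigmoid(w * 1 + b) fitted to target 1: every step moves the
  # prediction monotonically toward the target
  lm <- linear_classifier(1, seed = 2)
  data <- list(x = matrix(1, 1, 4), y = rep(1, 4))
  cfg <- train_config(inner_lr = 0.05, batch_size = 4, inner_steps = 25,
                      seed = 1)
  ep <- run_episode(lm, data, cfg, seed = 3)
  expect_true(all(diff(ep$losses) < 0))
  expect_lt(ep$losses[25], ep$losses[1] / 2)
  expect_error(run_episode(lm, data, cfg, steps = 0), "at least one")
  expect_error(run_episode(lm, list(x = matrix(0, 1, 0), y = numeric(0)),
                           cfg), "empty")
})

test_that("one episode step equals moment_update plus apply_update", {
  lm <- linear_classifier(3, seed = 5)
  data <- sep_features(6, d = 3)
  cfg <- train_config(batch_size = 6, inner_steps = 1, seed = 9)
  ep <- run_episode(lm, data, cfg, seed = 42)
  # manual composition with the same sampled batch
  manual <- with_seed(42, {
    pool <- sample.int(6)
    b <- prepare_batch(lm, data, pool, TRUE)
    g <- model_gradients(lm, b$x, b$y)
    st <- moment_update(moment_state(lm$params), g$grads, cfg$phi1, cfg$phi2)
    apply_update(lm$params, st, cfg$inner_lr, cfg$update_mode)
  })
  expect_equal(ep$model$params, manual, tolerance = 1e-14)
})

test_that("episodes are deterministic under a fixed seed", {
  lm <- linear_classifier(4, seed = 1)
  data <- sep_features(20, d = 4)
  cfg <- train_config(seed = 3, inner_steps = 5)
  e1 <- run_episode(lm, data, cfg, seed = 7)
  e2 <- run_episode(lm, data, cfg, seed = 7)
  expect_identical(e1$model$params, e2$model$params)
  expect_identical(e1$losses, e2$losses)
})

test_that("meta-training with one task equals plain episodic training", {
  lm <- linear_classifier(4, seed = 8)
  data <- sep_features(24, d = 4)
  cfg <- train_config(seed = 5, inner_steps = 4)
  task <- meta_task("dev", data, data)  # query = support
  mt <- meta_train(lm, list(task), cfg)
  # independent replay: two plain episodes with the same derived streams,
  # fresh moments at the episode boundary
  e1 <- run_episode(lm, data, cfg, seed = derive_seed(cfg$seed, "sup1"))
  e2 <- run_episode(e1$model, data, cfg, seed = derive_seed(cfg$seed, "que1"))
  expect_equal(mt$params, e2$model$params, tolerance = 1e-14)
  expect_error(meta_train(lm, list(), cfg), "at least one task")
})

test_that("meta-training reduces the loss on each device", {
  # three synthetic "devices": same class structure, shifted feature scales
  losses_drop <- vapply(1:5, function(seed) {
    tasks <- lapply(1:3, function(d) {
      ds <- sep_features(24, d = 6, shift = 1.5, seed = seed * 10 + d)
      sq <- split_support_query(ds$x, ds$y, 0.5, seed = seed + d)
      meta_task(paste0("dev", d), sq$support, sq$query)
    })
    lm <- linear_classifier(6, seed = seed)
    cfg <- train_config(inner_lr = 0.05, seed = seed, inner_steps = 8,
                        batch_size = 8)
    mt <- meta_train(lm, tasks, cfg)
    h <- attr(mt, "history")
    mean(h$last_loss) - mean(h$first_loss)
  }, 0)
  expect_lt(median(losses_drop), 0)
})

test_that("fine-tuning adapts to a new device and is reproducible", {
  gains <- vapply(1:10, function(seed) {
    tasks <- lapply(1:3, function(d) {
      ds <- sep_features(30, d = 6, shift = 1.2, seed = seed * 20 + d)
      sq <- split_support_query(ds$x, ds$y, 0.5, seed = seed + d)
      meta_task(paste0("dev", d), sq$support, sq$query)
    })
    lm <- linear_classifier(6, seed = seed)
    cfg <- train_config(inner_lr = 0.05, finetune_lr = 0.05,
                        finetune_steps = 20, batch_size = 8, seed = seed)
    mt <- meta_train(lm, tasks, cfg)
    # held-out device with a feature-scale shift
    new <- sep_features(40, d = 6, shift = 1.2, seed = seed * 31)
    new$x <- new$x * 0.5 + 0.3
    adapt <- list(x = new$x[, 1:10], y = new$y[1:10])
    test <- list(x = new$x[, 11:40], y = new$y[11:40])
    acc <- function(m) mean(predict_label(model_scores(m, test$x)) == test$y)
    ft <- fine_tune(mt, adapt, cfg)
    acc(ft) - acc(mt)
  }, 0)
  expect_gte(median(gains), 0)
  # bit-for-bit reproducibility in literal mode
  lm <- linear_classifier(3, seed = 2)
  ds <- sep_features(12, d = 3)
  cfg <- train_config(update_mode = "literal", finetune_steps = 5, seed = 4)
  f1 <- fine_tune(lm, ds, cfg)
  f2 <- fine_tune(lm, ds, cfg)
  expect_identical(f1$params, f2$params)
  # zero learning rate (guard bypassed inside the episode loop): no movement
  e0 <- run_episode(lm, ds, cfg, steps = 5, lr = 0, seed = 1)
  expect_identical(e0$model$params, lm$params)
})

test_that("a fine-tuned head separates linearly separable features", {
  # parameter-recovery property at the default fine-tuning step budget
  accs <- vapply(1:10, function(seed) {
    base <- build_hybrid_model(seed = seed)
    head <- head_model(base)
    ds <- sep_features(64, d = 1000, shift = 0.5, seed = seed)
    cfg <- train_config(seed = seed)  # T = 50 steps, adam defaults
    ft <- fine_tune(head, ds, cfg)
    ft <- recalibrate_bn(ft, ds, seed = seed)
    mean(predict_label(model_scores(ft, ds$x)) == ds$y)
  }, 0)
  expect_gte(median(accs), 0.95)
})

test_that("support/query splits honour fraction and overlap", {
  ds <- sep_features(20, d = 2)
  sq <- split_support_query(ds$x, ds$y, fraction = 0.5, seed = 3)
  expect_equal(ncol(sq$support$x), 10)
  expect_equal(ncol(sq$query$x), 10)
  # the two sets partition the samples when overlap = 0
  key <- function(m) apply(m, 2, paste, collapse = ",")
  expect_length(intersect(key(sq$support$x), key(sq$query$x)), 0)
  # with overlap, support samples reappear in the query set
  sqo <- split_support_query(ds$x, ds$y, fraction = 0.5, overlap = 0.4,
                             seed = 3)
  expect_equal(ncol(sqo$query$x), 14)
  expect_gt(length(intersect(key(sqo$support$x), key(sqo$query$x))), 0)
})

test_that("train_config enforces the paper's constants", {
  cfg <- train_config()
  expect_equal(cfg$epsilon, 1e-8)
  expect_equal(cfg$inner_lr, 0.01)
  expect_equal(cfg$finetune_lr, 0.001)
  expect_equal(cfg$phi1, 0.9)
  expect_equal(cfg$phi2, 0.999)
  expect_error(train_config(phi1 = 1))
  expect_error(train_config(inner_lr = 0))
})
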