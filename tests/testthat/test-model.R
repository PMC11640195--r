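tiny_transform <- function() transform_config(36, 32, mode = "train", seed = 1)

test_that("the hybrid forward pass honours its contracts", {
  m <- build_hybrid_model(transform = tiny_transform(), seed = 3)
  set.seed(1)
  x <- array(rnorm(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  p <- model_scores(m, x)
  expect_length(p, 4)
  expect_true(all(p > 0 & p < 1))
  # batch order preserved: permuting inputs permutes outputs
  perm <- c(3, 1, 4, 2)
  expect_equal(model_scores(m, x[, , , perm, drop = FALSE]), p[perm],
               tolerance = 1e-12)
  # wrong input rank is a shape error
  expect_error(model_scores(m, x[, , , 1]), "array")
  # the backbone feature has length 1000
  f <- hybrid_features(m, x)
  expect_equal(dim(f), c(1000, 4))
  # two builds with the same seed are identical; different seeds differ
  m2 <- build_hybrid_model(transform = tiny_transform(), seed = 3)
  expect_identical(m$params, m2$params)
  m3 <- build_hybrid_model(transform = tiny_transform(), seed = 4)
  expect_false(identical(m$params, m3$params))
})

test_that("the head computes what its table of layers says", {
  m <- build_hybrid_model(seed = 5)
  # layer shapes: 1000 -> 1024 -> 512 -> 1
  expect_equal(dim(m$params$head.fc1.w), c(1024, 1000))
  expect_equal(dim(m$params$head.fc2.w), c(512, 1024))
  expect_equal(dim(m$params$head.fc3.w), c(1, 512))
  # all-zero weights and biases give Sigmoid(0) = 0.5
  mz <- m
  for (nm in grep("^head\\.(fc|p)", names(mz$params), value = TRUE))
    mz$params[[nm]] <- mz$params[[nm]] * 0
  f <- matrix(rnorm(1000 * 3), 1000)
  expect_equal(basenet_forward(f, mz), rep(0.5, 3))
  # evaluation mode is deterministic (dropout off)
  p1 <- basenet_forward(f, m)
  expect_identical(p1, basenet_forward(f, m))
  expect_error(basenet_forward(matrix(0, 10, 2), m), "1000")
  # head_model reproduces the hybrid's head on the hybrid's own features
  set.seed(2)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  m$transform <- tiny_transform()
  feats <- hybrid_features(m, x)
  expect_equal(model_scores(head_model(m), feats), model_scores(m, x),
               tolerance = 1e-12)
})

test_that("predict_label applies the threshold with ties positive", {
  expect_equal(predict_label(c(0.7, 0.5, 0.49), 0.5), c(1L, 1L, 0L))
  expect_error(predict_label(0.5, 0))
})

test_that("analytic gradients match central finite differences", {
  m <- build_hybrid_model(hcfg = basenet_config(dropout_p = 0),
                          transform = tiny_transform(), seed = 3)
  set.seed(4)
  x <- array(rnorm(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  y <- c(0, 1, 1, 0)
  g0 <- model_gradients(m, x, y)
  fd_check <- function(nm, i, tol = 1e-4) {
    eps <- 1e-5
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    fd <- (model_gradients(mp, x, y)$loss -
             model_gradients(mm, x, y)$loss) / (2 * eps)
    expect_equal(g0$grads[[nm]][i], fd, tolerance = tol)
  }
  fd_check("head.fc3.b", 1)       # final bias
  fd_check("head.fc1.w", 5)
  fd_check("head.p1", 1)          # learnable activation slope
  fd_check("stem.conv.w", 10)
  fd_check("s2.b1.conv1.w", 11)
  fd_check("s3.b1.down.w", 2)
  fd_check("s1.b2.bn1.g", 3)
})

test_that("gradients exist for every parameter and match shapes", {
  m <- build_hybrid_model(transform = tiny_transform(), seed = 7)
  set.seed(5)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  set.seed(9)
  g <- model_gradients(m, x, c(0, 1))
  expect_identical(names(g$grads), names(m$params))
  expect_true(all(mapply(function(a, b) length(a) == length(b),
                         g$grads, m$params)))
  expect_gte(g$loss, 0)
})

test_that("a checkpoint round-trips the model", {
  m <- build_hybrid_model(transform = tiny_transform(), seed = 13)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$buffers, m$buffers)
  set.seed(3)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_identical(model_scores(m, x), model_scores(m2, x))
})

test_that("predict() applies the evaluation transform to raw images", {
  m <- build_hybrid_model(transform = tiny_transform(), seed = 2)
  imgs <- list(a = blob_image(seed = 1), b = blob_image(seed = 2, label = 0))
  pr <- predict(m, imgs)
  expect_length(pr, 2)
  expect_true(all(pr > 0 & pr < 1))
  lb <- predict(m, imgs, type = "label")
  expect_equal(lb, predict_label(pr))
})

test_that("linear classifier gradients match finite differences", {
  lm <- linear_classifier(5, seed = 1)
  set.seed(2)
  x <- matrix(rnorm(15), 5)
  y <- c(1, 0, 1)
  g <- model_gradients(lm, x, y)
  eps <- 1e-6
  for (i in 1:5) {
    lp <- lm; lp$params$w[i] <- lp$params$w[i] + eps
    lmn <- lm; lmn$params$w[i] <- lmn$params$w[i] - eps
    fd <- (model_gradients(lp, x, y)$loss -
             model_gradients(lmn, x, y)$loss) / (2 * eps)
    expect_equal(g$grads$w[i], fd, tolerance = 1e-6)
  }
})

test_that("pretrained weights are clearly unavailable", {
  expect_error(backbone_config(pretrained = TRUE), "pretrained")
})
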