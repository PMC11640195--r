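#' Backbone configuration (18-layer residual network)
#'
#' The backbone is the classic 18-layer residual design: a 7x7/2 stem
#' convolution, a 3x3/2 pooling layer, four stages of two residual blocks
#' each (64/128/256/512 channels, stages 2-4 downsampling by 2 with a 1x1
#' projection on the skip path), global average pooling, and a final fully
#' connected layer producing the 1000-dimensional feature consumed by the
#' head. The stem pool is average pooling by default (`"max"` is available
#' for compatibility with the canonical design).
#'
#' @param pool_type `"average"` (default) or `"max"` stem pooling.
#' @param zero_init_residual Initialize the scale of each block's final
#'   normalization layer to zero so every residual block starts as the
#'   identity. This makes from-scratch training stable at the default
#'   learning rate and is the default.
#' @param pretrained Reserved flag; no bundled weights, must be `FALSE`.
#' @return A `backbone_config` object.
#' @export
backbone_config <- function(pool_type = c("average", "max"),
                            zero_init_residual = TRUE,
                            pretrained = FALSE) {
  pool_type <- match.arg(pool_type)
  if (isTRUE(pretrained))
    stop("no pretrained backbone weights are bundled; use pretrained = FALSE")
  structure(list(stem_kernel = 7L, stem_stride = 2L, stem_padding = 3L,
                 pool_kernel = 3L, pool_stride = 2L, pool_padding = 1L,
                 pool_type = pool_type, stages = 4L, blocks_per_stage = 2L,
                 channels = c(64L, 128L, 256L, 512L), feature_dim = 1000L,
                 zero_init_residual = isTRUE(zero_init_residual),
                 pretrained = FALSE),
            class = "backbone_config")
}

#' Head configuration (three fully connected layers)
#'
#' The head maps the 1000-dimensional backbone feature to a fumigation
#' probability: FC1 (1000 to 1024), BN1, PReLU, Drop1, FC2 (1024 to 512),
#' BN2, PReLU, Drop2, FC3 (512 to 1), Sigmoid. The layer sizes are fixed;
#' only the dropout rate is tunable.
#'
#' @param dropout_p Dropout probability in `[0, 1)` (default 0.5).
#' @return A `basenet_config` object.
#' @export
basenet_config <- function(dropout_p = 0.5) {
  stopifnot(dropout_p >= 0, dropout_p < 1)
  structure(list(dims = c(1000L, 1024L, 512L, 1L), dropout_p = dropout_p),
            class = "basenet_config")
}

p_ <- function(...) paste(..., sep = ".")

.stage_plan <- function(bcfg) {
  plan <- list()
  in_ch <- bcfg$channels[1]
  for (s in seq_len(bcfg$stages)) {
    out_ch <- bcfg$channels[s]
    for (b in seq_len(bcfg$blocks_per_stage)) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      plan[[length(plan) + 1L]] <- list(
        pfx = sprintf("s%d.b%d", s, b), in_ch = in_ch, out_ch = out_ch,
        stride = stride, down = (stride != 1L || in_ch != out_ch))
      in_ch <- out_ch
    }
  }
  plan
}

.he_init <- function(dims, fan_in) array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)

init_hybrid_params <- function(bcfg, hcfg, seed) {
  with_seed(seed, {
    P <- list()
    Bu <- list()
    add_bn <- function(nm, ch) {
      P[[p_(nm, "g")]] <<- rep(1, ch)
      P[[p_(nm, "b")]] <<- rep(0, ch)
      Bu[[p_(nm, "rm")]] <<- rep(0, ch)
      Bu[[p_(nm, "rv")]] <<- rep(1, ch)
    }
    k <- bcfg$stem_kernel
    P[["stem.conv.w"]] <- .he_init(c(k, k, 3, bcfg$channels[1]), k * k * 3)
    add_bn("stem.bn", bcfg$channels[1])
    for (bl in .stage_plan(bcfg)) {
      P[[p_(bl$pfx, "conv1.w")]] <-
        .he_init(c(3, 3, bl$in_ch, bl$out_ch), 9 * bl$in_ch)
      add_bn(p_(bl$pfx, "bn1"), bl$out_ch)
      P[[p_(bl$pfx, "conv2.w")]] <-
        .he_init(c(3, 3, bl$out_ch, bl$out_ch), 9 * bl$out_ch)
      add_bn(p_(bl$pfx, "bn2"), bl$out_ch)
      if (bcfg$zero_init_residual)
        P[[p_(bl$pfx, "bn2.g")]] <- rep(0, bl$out_ch)
      if (bl$down) {
        P[[p_(bl$pfx, "down.w")]] <-
          .he_init(c(1, 1, bl$in_ch, bl$out_ch), bl$in_ch)
        add_bn(p_(bl$pfx, "dbn"), bl$out_ch)
      }
    }
    cf <- bcfg$channels[bcfg$stages]
    P[["fc.w"]] <- matrix(rnorm(bcfg$feature_dim * cf, sd = sqrt(2 / cf)),
                          bcfg$feature_dim, cf)
    P[["fc.b"]] <- rep(0, bcfg$feature_dim)
    d <- hcfg$dims
    for (i in 1:3) {
      P[[sprintf("head.fc%d.w", i)]] <-
        matrix(rnorm(d[i + 1] * d[i], sd = sqrt(2 / d[i])), d[i + 1], d[i])
      P[[sprintf("head.fc%d.b", i)]] <- rep(0, d[i + 1])
    }
    add_bn("head.bn1", d[2])
    add_bn("head.bn2", d[3])
    P[["head.p1"]] <- 0.25
    P[["head.p2"]] <- 0.25
    list(params = P, buffers = Bu)
  })
}

#' Build the hybrid classifier
#'
#' Assembles the residual backbone and the fully connected head into one
#' model whose forward pass maps a standardized RGB crop to a fumigation
#' probability in (0, 1). Initialization is deterministic under `seed`
#' (He-scaled Gaussians for weights, unit/zero batch-norm parameters,
#' PReLU slopes at 0.25).
#'
#' @param bcfg A [backbone_config()].
#' @param hcfg A [basenet_config()].
#' @param seed Integer seed for parameter initialization.
#' @param transform Optional [transform_config()] describing the input
#'   preparation this model expects (carried along for `predict`).
#' @return An object of class `hybrid_model` with elements `params`
#'   (named list of parameter arrays), `buffers` (batch-norm running
#'   statistics), `bcfg`, `hcfg`, `transform`.
#' @export
build_hybrid_model <- function(bcfg = backbone_config(),
                               hcfg = basenet_config(), seed = 1,
                               transform = NULL) {
  stopifnot(inherits(bcfg, "backbone_config"), inherits(hcfg, "basenet_config"))
  ini <- init_hybrid_params(bcfg, hcfg, seed)
  structure(list(params = ini$params, buffers = ini$buffers,
                 bcfg = bcfg, hcfg = hcfg, transform = transform,
                 seed = seed),
            class = "hybrid_model")
}

# Forward pass. When `training` is TRUE, intermediate activations are stored
# in environment E for the backward pass and batch-norm running statistics
# are updated in E$Bu.
.hybrid_forward <- function(model, x, training = FALSE, E = NULL) {
  if (length(dim(x)) != 4L || dim(x)[3] != 3L)
    stop("input must be a (H, W, 3, N) array of standardized crops")
  P <- model$params
  keep <- !is.null(E)
  if (keep) { E$Bu <- model$buffers; E$cache <- list() }
  Bu <- model$buffers
  bn <- function(nm, z) {
    r <- bn2d_forward(z, P[[p_(nm, "g")]], P[[p_(nm, "b")]],
                      Bu[[p_(nm, "rm")]], Bu[[p_(nm, "rv")]], training)
    if (keep) {
      E$cache[[nm]] <- r$cache
      E$Bu[[p_(nm, "rm")]] <- r$rm
      E$Bu[[p_(nm, "rv")]] <- r$rv
    }
    r$y
  }
  st <- function(nm, val) if (keep) E$cache[[nm]] <- val

  z <- cpp_conv2d_forward(x, P[["stem.conv.w"]], model$bcfg$stem_stride,
                          model$bcfg$stem_padding)
  st("stem.in", x)
  zb <- bn("stem.bn", z)
  r <- relu_forward(zb); st("stem.relu.mask", r$mask)
  if (model$bcfg$pool_type == "average") {
    a <- cpp_avgpool_forward(r$y, model$bcfg$pool_kernel,
                             model$bcfg$pool_stride, model$bcfg$pool_padding)
    st("stem.pool.indims", dim(r$y))
  } else {
    mp <- cpp_maxpool_forward(r$y, model$bcfg$pool_kernel,
                              model$bcfg$pool_stride, model$bcfg$pool_padding)
    a <- mp$y
    st("stem.pool.indims", dim(r$y)); st("stem.pool.idx", mp$idx)
  }

  for (bl in .stage_plan(model$bcfg)) {
    pfx <- bl$pfx
    st(p_(pfx, "in"), a)
    z1 <- cpp_conv2d_forward(a, P[[p_(pfx, "conv1.w")]], bl$stride, 1L)
    b1 <- bn(p_(pfx, "bn1"), z1)
    r1 <- relu_forward(b1)
    st(p_(pfx, "relu1.mask"), r1$mask); st(p_(pfx, "r1"), r1$y)
    z2 <- cpp_conv2d_forward(r1$y, P[[p_(pfx, "conv2.w")]], 1L, 1L)
    b2 <- bn(p_(pfx, "bn2"), z2)
    sk <- if (bl$down) {
      zd <- cpp_conv2d_forward(a, P[[p_(pfx, "down.w")]], bl$stride, 0L)
      bn(p_(pfx, "dbn"), zd)
    } else a
    s <- b2 + sk
    r2 <- relu_forward(s)
    st(p_(pfx, "relu2.mask"), r2$mask)
    a <- r2$y
  }

  st("gap.indims", dim(a))
  g <- gap_forward(a)
  st("fc.in", g)
  feat <- fc_forward(g, P[["fc.w"]], P[["fc.b"]])

  hp <- .basenet_forward_raw(P, Bu, model$hcfg, feat, training, E)
  if (keep) E$feat <- feat
  hp
}

# Head forward on a (1000, N) feature matrix; shares the cache mechanism.
.basenet_forward_raw <- function(P, Bu, hcfg, feat, training, E = NULL) {
  keep <- !is.null(E)
  st <- function(nm, val) if (keep) E$cache[[nm]] <- val
  bn1 <- function(nm, z) {
    r <- bn1d_forward(z, P[[p_(nm, "g")]], P[[p_(nm, "b")]],
                      Bu[[p_(nm, "rm")]], Bu[[p_(nm, "rv")]], training)
    if (keep) {
      E$cache[[nm]] <- r$cache
      E$Bu[[p_(nm, "rm")]] <- r$rm
      E$Bu[[p_(nm, "rv")]] <- r$rv
    }
    r$y
  }
  st("head.in", feat)
  h1 <- fc_forward(feat, P[["head.fc1.w"]], P[["head.fc1.b"]])
  hb1 <- bn1("head.bn1", h1)
  pr1 <- prelu_forward(hb1, P[["head.p1"]])
  st("head.prelu1", list(x = hb1, pos = pr1$pos))
  dr1 <- dropout_forward(pr1$y, hcfg$dropout_p, training)
  st("head.drop1.mask", dr1$mask); st("head.d1", dr1$y)
  h2 <- fc_forward(dr1$y, P[["head.fc2.w"]], P[["head.fc2.b"]])
  hb2 <- bn1("head.bn2", h2)
  pr2 <- prelu_forward(hb2, P[["head.p2"]])
  st("head.prelu2", list(x = hb2, pos = pr2$pos))
  dr2 <- dropout_forward(pr2$y, hcfg$dropout_p, training)
  st("head.drop2.mask", dr2$mask); st("head.d2", dr2$y)
  z <- fc_forward(dr2$y, P[["head.fc3.w"]], P[["head.fc3.b"]])
  prob <- 1 / (1 + exp(-z))
  st("prob", prob)
  as.numeric(prob)
}

# Backward through the head from d(loss)/d(prob); fills G (an environment
# used as a mutable gradient store) and returns d(loss)/d(feature).
.basenet_backward <- function(P, cache, dprob, G) {
  prob <- cache$prob
  dz <- matrix(dprob * prob * (1 - prob), 1)
  fcb <- function(nm, dy, xin) {
    r <- fc_backward(dy, xin, P[[p_(nm, "w")]])
    G[[p_(nm, "w")]] <- r$dw
    G[[p_(nm, "b")]] <- r$db
    r$dx
  }
  bnb1 <- function(nm, dy) {
    r <- bn1d_backward(dy, P[[p_(nm, "g")]], cache[[nm]])
    G[[p_(nm, "g")]] <- r$dg
    G[[p_(nm, "b")]] <- r$db
    r$dx
  }
  dd2 <- fcb("head.fc3", dz, cache$head.d2)
  if (!is.null(cache$head.drop2.mask)) dd2 <- dd2 * cache$head.drop2.mask
  pr2 <- cache$head.prelu2
  pb2 <- prelu_backward(dd2, pr2$x, P[["head.p2"]], pr2$pos)
  G[["head.p2"]] <- pb2$da
  dh2 <- bnb1("head.bn2", pb2$dx)
  dd1 <- fcb("head.fc2", dh2, cache$head.d1)
  if (!is.null(cache$head.drop1.mask)) dd1 <- dd1 * cache$head.drop1.mask
  pr1 <- cache$head.prelu1
  pb1 <- prelu_backward(dd1, pr1$x, P[["head.p1"]], pr1$pos)
  G[["head.p1"]] <- pb1$da
  dh1 <- bnb1("head.bn1", pb1$dx)
  fcb("head.fc1", dh1, cache$head.in)
}

# Backward pass from d(loss)/d(prob); returns gradients for every parameter.
.hybrid_backward <- function(model, E, dprob) {
  P <- model$params
  G <- new.env(parent = emptyenv())
  cache <- E$cache

  fcb <- function(nm, dy, xin) {
    r <- fc_backward(dy, xin, P[[p_(nm, "w")]])
    G[[p_(nm, "w")]] <- r$dw
    G[[p_(nm, "b")]] <- r$db
    r$dx
  }
  bnb2 <- function(nm, dy) {
    r <- bn2d_backward(dy, P[[p_(nm, "g")]], cache[[nm]])
    G[[p_(nm, "g")]] <- r$dg
    G[[p_(nm, "b")]] <- r$db
    r$dx
  }

  dfeat <- .basenet_backward(P, cache, dprob, G)
  dg <- fcb("fc", dfeat, cache$fc.in)
  da <- gap_backward(dg, cache$gap.indims)

  for (bl in rev(.stage_plan(model$bcfg))) {
    pfx <- bl$pfx
    ds <- da * cache[[p_(pfx, "relu2.mask")]]
    db2 <- bnb2(p_(pfx, "bn2"), ds)
    cb2 <- cpp_conv2d_backward(cache[[p_(pfx, "r1")]],
                               P[[p_(pfx, "conv2.w")]], db2, 1L, 1L)
    G[[p_(pfx, "conv2.w")]] <- cb2$dw
    dr1 <- cb2$dx * cache[[p_(pfx, "relu1.mask")]]
    db1 <- bnb2(p_(pfx, "bn1"), dr1)
    cb1 <- cpp_conv2d_backward(cache[[p_(pfx, "in")]],
                               P[[p_(pfx, "conv1.w")]], db1, bl$stride, 1L)
    G[[p_(pfx, "conv1.w")]] <- cb1$dw
    da <- cb1$dx
    if (bl$down) {
      dbd <- bnb2(p_(pfx, "dbn"), ds)
      cbd <- cpp_conv2d_backward(cache[[p_(pfx, "in")]],
                                 P[[p_(pfx, "down.w")]], dbd, bl$stride, 0L)
      G[[p_(pfx, "down.w")]] <- cbd$dw
      da <- da + cbd$dx
    } else {
      da <- da + ds
    }
  }

  if (model$bcfg$pool_type == "average") {
    dr <- cpp_avgpool_backward(da, cache$stem.pool.indims,
                               model$bcfg$pool_kernel, model$bcfg$pool_stride,
                               model$bcfg$pool_padding)
  } else {
    dr <- cpp_maxpool_backward(da, cache$stem.pool.idx, cache$stem.pool.indims)
  }
  dzb <- dr * cache$stem.relu.mask
  dstem <- bnb2("stem.bn", dzb)
  cbs <- cpp_conv2d_backward(cache$stem.in, P[["stem.conv.w"]], dstem,
                             model$bcfg$stem_stride, model$bcfg$stem_padding)
  G[["stem.conv.w"]] <- cbs$dw
  mget(names(model$params), envir = G)
}

#' Head forward pass on 1000-dimensional features
#'
#' Applies FC1, BN1, PReLU, Drop1, FC2, BN2, PReLU, Drop2, FC3, Sigmoid to a
#' feature batch. Dropout is active only when `training = TRUE` (it draws
#' from the ambient RNG stream).
#'
#' @param feature Numeric matrix `(1000, N)` or a length-1000 vector.
#' @param model A [build_hybrid_model()] object holding the head weights.
#' @param training Logical; enables dropout and batch statistics.
#' @return Numeric vector of `N` probabilities in (0, 1).
#' @export
basenet_forward <- function(feature, model, training = FALSE) {
  if (is.null(dim(feature))) feature <- matrix(feature, ncol = 1)
  if (nrow(feature) != model$hcfg$dims[1])
    stop(sprintf("feature dimension must be %d", model$hcfg$dims[1]))
  .basenet_forward_raw(model$params, model$buffers, model$hcfg, feature,
                       training, NULL)
}

#' Backbone feature for a batch of standardized crops
#'
#' Runs the residual backbone in evaluation mode up to (and including) its
#' final fully connected layer, returning the 1000-dimensional feature fed
#' to the head.
#'
#' @param model A `hybrid_model`.
#' @param x `(H, W, 3, N)` array of standardized crops.
#' @return Numeric matrix `(1000, N)`.
#' @export
hybrid_features <- function(model, x) {
  E <- new.env(parent = emptyenv())
  .hybrid_forward(model, x, training = FALSE, E = E)
  E$feat
}

#' Turn a probability into a discrete class label
#'
#' Label 1 (sulfur-fumigated) if the probability is greater than or equal to
#' the threshold, otherwise 0; the boundary is assigned to the positive
#' class.
#'
#' @param probability Numeric vector of probabilities.
#' @param threshold Decision threshold in (0, 1).
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(probability, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  as.integer(probability >= threshold)
}

# ---- generic model interface used by the meta-optimizer -------------------

#' Loss and gradients for one minibatch
#'
#' Generic used by [run_episode()]: runs a training-mode forward pass,
#' computes the mean-squared-error loss against the 0/1 targets, and returns
#' the loss, per-parameter gradients, and the model with updated batch-norm
#' running statistics.
#'
#' @param model A model object (`hybrid_model` or `linear_classifier`).
#' @param x Input batch in the model's native format.
#' @param y Numeric 0/1 target vector.
#' @param ... Unused.
#' @return List with `loss`, `grads` (named like `model$params`), `model`.
#' @export
model_gradients <- function(model, x, y, ...) UseMethod("model_gradients")

#' @export
model_gradients.hybrid_model <- function(model, x, y, ...) {
  n <- dim(x)[4]
  stopifnot(length(y) == n, n >= 1)
  E <- new.env(parent = emptyenv())
  prob <- .hybrid_forward(model, x, training = TRUE, E = E)
  loss <- mean((prob - y)^2)
  dprob <- 2 * (prob - y) / n
  grads <- .hybrid_backward(model, E, dprob)
  model$buffers <- E$Bu
  list(loss = loss, grads = grads, model = model, prob = prob)
}

#' Classification scores in evaluation mode
#'
#' @param model A model object.
#' @param x Input batch in the model's native format.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
model_scores <- function(model, x, ...) UseMethod("model_scores")

#' @export
model_scores.hybrid_model <- function(model, x, ...) {
  .hybrid_forward(model, x, training = FALSE, E = NULL)
}

# ---- head-only model on frozen backbone features ---------------------------

#' Extract the classifier head as a standalone model
#'
#' Returns the fully connected head of a (typically meta-trained) hybrid
#' model as a model in its own right, operating on `(1000, N)` feature
#' matrices (see [extract_features()]). Training it is the cheap,
#' frozen-backbone form of device adaptation used by the scaled-down
#' training-ratio sweep.
#'
#' @param model A `hybrid_model`.
#' @return A `basenet_model` with the head's parameters and running
#'   statistics.
#' @export
head_model <- function(model) {
  stopifnot(inherits(model, "hybrid_model"))
  keep <- grepl("^head\\.", names(model$params))
  structure(list(params = model$params[keep],
                 buffers = model$buffers[grepl("^head\\.",
                                               names(model$buffers))],
                 hcfg = model$hcfg),
            class = "basenet_model")
}

#' @export
model_gradients.basenet_model <- function(model, x, y, ...) {
  n <- ncol(x)
  stopifnot(nrow(x) == model$hcfg$dims[1], length(y) == n)
  E <- new.env(parent = emptyenv())
  E$Bu <- model$buffers
  E$cache <- list()
  prob <- .basenet_forward_raw(model$params, model$buffers, model$hcfg, x,
                               training = TRUE, E = E)
  loss <- mean((prob - y)^2)
  G <- new.env(parent = emptyenv())
  .basenet_backward(model$params, E$cache, 2 * (prob - y) / n, G)
  model$buffers <- E$Bu
  list(loss = loss, grads = mget(names(model$params), envir = G),
       model = model, prob = prob)
}

#' @export
model_scores.basenet_model <- function(model, x, ...) {
  .basenet_forward_raw(model$params, model$buffers, model$hcfg, x,
                       training = FALSE, NULL)
}

#' Backbone features for a manifest of images
#'
#' Applies the model's evaluation transform and backbone to every image and
#' returns the 1000-dimensional features as a matrix with one named column
#' per sample.
#'
#' @param model A `hybrid_model` with a transform configuration.
#' @param images Named list of RGB arrays.
#' @param batch_size Evaluation batch size.
#' @return Numeric matrix `(1000, length(images))`, columns named like
#'   `images`.
#' @export
extract_features <- function(model, images, batch_size = 32) {
  cfg <- model$transform
  stopifnot(!is.null(cfg))
  cfg$mode <- "eval"
  side <- cfg$crop_side
  n <- length(images)
  out <- matrix(0, model$bcfg$feature_dim, n,
                dimnames = list(NULL, names(images)))
  for (i in seq(1, n, by = batch_size)) {
    j <- min(i + batch_size - 1, n)
    tens <- lapply(images[i:j], eval_transform, cfg = cfg)
    xb <- array(unlist(tens, use.names = FALSE), c(side, side, 3, j - i + 1))
    out[, i:j] <- hybrid_features(model, xb)
  }
  out
}

# ---- a light linear model implementing the same interface -----------------

#' Linear sigmoid classifier on feature vectors
#'
#' A single linear layer with sigmoid output implementing the same training
#' interface as the hybrid model. Used as a fast reference model for the
#' meta-optimizer's behavioural tests and as a cheap baseline on feature
#' data; inputs are `(features, N)` matrices.
#'
#' @param n_features Input dimension.
#' @param seed Integer seed for the initialization.
#' @param init_sd Standard deviation of the Gaussian weight initialization;
#'   defaults to `sqrt(1 / n_features)`. Use 0 for a zero-initialized
#'   (deterministic) probe — with high-dimensional, large-magnitude
#'   features a random projection can saturate the sigmoid at the start,
#'   stalling the mean-squared-error gradient.
#' @return An object of class `linear_classifier`.
#' @export
linear_classifier <- function(n_features, seed = 1, init_sd = NULL) {
  init_sd <- init_sd %||% sqrt(1 / n_features)
  with_seed(seed, {
    structure(list(params = list(
      w = matrix(if (init_sd > 0) rnorm(n_features, sd = init_sd) else
        numeric(n_features), 1),
      b = 0),
      buffers = list(), n_features = n_features),
      class = "linear_classifier")
  })
}

#' @export
model_gradients.linear_classifier <- function(model, x, y, ...) {
  n <- ncol(x)
  z <- model$params$w %*% x + model$params$b
  prob <- 1 / (1 + exp(-z))
  loss <- mean((prob - y)^2)
  dz <- (2 * (prob - y) / n) * prob * (1 - prob)
  list(loss = loss,
       grads = list(w = tcrossprod(dz, x), b = sum(dz)),
       model = model, prob = as.numeric(prob))
}

#' @export
model_scores.linear_classifier <- function(model, x, ...) {
  as.numeric(1 / (1 + exp(-(model$params$w %*% x + model$params$b))))
}

# ---- S3 conveniences -------------------------------------------------------

#' @export
print.hybrid_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat("Hybrid sulfur-fumigation classifier\n")
  cat(sprintf("  backbone: 18-layer residual (%s stem pool), feature dim %d\n",
              x$bcfg$pool_type, x$bcfg$feature_dim))
  cat(sprintf("  head: %s, dropout %.2f\n",
              paste(x$hcfg$dims, collapse = " -> "), x$hcfg$dropout_p))
  cat(sprintf("  parameters: %s values in %d arrays\n",
              format(np, big.mark = ","), length(x$params)))
  invisible(x)
}

#' @export
summary.hybrid_model <- function(object, ...) {
  print(object)
  hist <- attr(object, "history")
  if (!is.null(hist)) {
    cat("training history (episode mean losses):\n")
    print(hist, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.hybrid_model <- function(object, ...) object$params

#' Predict fumigation probabilities or labels for raw images
#'
#' Applies the model's evaluation transform (deterministic resize, center
#' crop, standardization) to each image and runs the forward pass in
#' evaluation mode.
#'
#' @param object A `hybrid_model` with a non-`NULL` `transform`.
#' @param newdata A list of RGB image arrays, or a single `(H, W, 3)` array.
#' @param type `"prob"` (default) or `"label"`.
#' @param threshold Decision threshold for `type = "label"`.
#' @param batch_size Evaluation minibatch size.
#' @param ... Unused.
#' @return Numeric probabilities or integer labels.
#' @export
predict.hybrid_model <- function(object, newdata, type = c("prob", "label"),
                                 threshold = 0.5, batch_size = 32, ...) {
  type <- match.arg(type)
  if (is.null(object$transform))
    stop("model carries no transform configuration; use model_scores()")
  if (!is.list(newdata)) newdata <- list(newdata)
  cfg <- object$transform
  cfg$mode <- "eval"
  tens <- lapply(newdata, eval_transform, cfg = cfg)
  probs <- numeric(length(tens))
  side <- cfg$crop_side
  for (i in seq(1, length(tens), by = batch_size)) {
    j <- min(i + batch_size - 1, length(tens))
    xb <- array(unlist(tens[i:j], use.names = FALSE), c(side, side, 3, j - i + 1))
    probs[i:j] <- model_scores(object, xb)
  }
  if (type == "prob") probs else predict_label(probs, threshold)
}

#' Recalibrate batch-normalization running statistics
#'
#' After rapid parameter movement the exponential running statistics lag
#' behind the activations the updated weights actually produce, which
#' degrades evaluation-mode predictions. This refreshes them by running
#' training-mode forward passes (no parameter updates) over minibatches of
#' `data`; the statistics converge to the current activation distribution.
#' Called by the pipeline after every training phase, before evaluation,
#' using training-side data only.
#'
#' @param model A `hybrid_model` or `basenet_model`.
#' @param data Dataset list (`x`, `y`) to draw calibration batches from.
#' @param batches Number of forward passes (ignored when `deterministic`).
#' @param batch_size Calibration batch size.
#' @param seed Integer seed for batch sampling and augmentation.
#' @param deterministic If `TRUE`, make one sequential pass over `data` in
#'   its given order using the deterministic evaluation preparation (no
#'   augmentation, no sampling), so the refreshed statistics are a pure
#'   function of the model and the data.
#' @return The model with refreshed running statistics.
#' @export
recalibrate_bn <- function(model, data, batches = 10, batch_size = 16,
                           seed = 1, deterministic = FALSE) {
  if (!inherits(model, c("hybrid_model", "basenet_model"))) return(model)
  n <- validate_dataset(data)
  one_pass <- function(idx) {
    b <- prepare_batch(model, data, idx, train = !deterministic)
    E <- new.env(parent = emptyenv())
    E$Bu <- model$buffers
    E$cache <- list()
    if (inherits(model, "hybrid_model")) {
      invisible(.hybrid_forward(model, b$x, training = TRUE, E = E))
    } else {
      invisible(.basenet_forward_raw(model$params, model$buffers,
                                     model$hcfg, b$x, training = TRUE,
                                     E = E))
    }
    model$buffers <<- E$Bu
  }
  if (deterministic) {
    for (i in seq(1, n, by = batch_size)) one_pass(i:min(i + batch_size - 1, n))
  } else {
    with_seed(seed, {
      for (i in seq_len(batches)) one_pass(sample.int(n, min(batch_size, n)))
    })
  }
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the named parameter
#' arrays, batch-norm running statistics, both configurations and the
#' transform; `load_checkpoint(save_checkpoint(m, f))` restores an
#' equivalent model.
#'
#' @param model A `hybrid_model`.
#' @param path File path for the checkpoint.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `hybrid_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(params = model$params, buffers = model$buffers,
               bcfg = model$bcfg, hcfg = model$hcfg,
               transform = model$transform, seed = model$seed,
               history = attr(model, "history")), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  m <- structure(list(params = obj$params, buffers = obj$buffers,
                      bcfg = obj$bcfg, hcfg = obj$hcfg,
                      transform = obj$transform, seed = obj$seed),
                 class = "hybrid_model")
  attr(m, "history") <- obj$history
  m
}
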