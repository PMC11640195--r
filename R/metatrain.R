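#' Meta-training configuration
#'
#' Hyperparameters of the episodic meta-optimizer. The update rule keeps
#' exponential moving averages of the gradient (first moment, decay `phi1`)
#' and its square (second moment, decay `phi2`) and subtracts a moment-based
#' step at every gradient update. `update_mode = "adam"` (default) uses the
#' standard stabilized step `lr * m / (sqrt(v) + epsilon)`;
#' `update_mode = "literal"` uses `lr * m / (epsilon + v)` (no square root),
#' which is numerically explosive for small gradients and provided for
#' comparison. No bias correction is applied in either mode.
#'
#' @param inner_lr Learning rate of the episodic (support/query) updates.
#' @param finetune_lr Learning rate used when adapting to a new device.
#' @param phi1,phi2 Exponential decay rates of the first/second moments,
#'   both in (0, 1).
#' @param epsilon Stability constant (fixed at 1e-8).
#' @param inner_steps Gradient updates per episode (`O`).
#' @param finetune_steps Gradient updates during fine-tuning (`T`).
#' @param batch_size Minibatch size within an episode.
#' @param update_mode `"adam"` or `"literal"`.
#' @param support_fraction Fraction of a device's images placed in the
#'   support set.
#' @param overlap Fraction of support images additionally shared with the
#'   query set (the sets need not be disjoint).
#' @param seed Integer seed from which all episode streams derive.
#' @return A `train_config` object.
#' @export
train_config <- function(inner_lr = 0.01, finetune_lr = 0.001,
                         phi1 = 0.9, phi2 = 0.999, epsilon = 1e-8,
                         inner_steps = 10, finetune_steps = 50,
                         batch_size = 16, update_mode = c("adam", "literal"),
                         support_fraction = 0.5, overlap = 0, seed = 1) {
  update_mode <- match.arg(update_mode)
  stopifnot(inner_lr > 0, finetune_lr > 0,
            phi1 > 0, phi1 < 1, phi2 > 0, phi2 < 1, epsilon > 0,
            inner_steps >= 1, finetune_steps >= 1, batch_size >= 1,
            support_fraction > 0, support_fraction < 1,
            overlap >= 0, overlap <= 1)
  structure(list(inner_lr = inner_lr, finetune_lr = finetune_lr,
                 phi1 = phi1, phi2 = phi2, epsilon = epsilon,
                 inner_steps = as.integer(inner_steps),
                 finetune_steps = as.integer(finetune_steps),
                 batch_size = as.integer(batch_size),
                 update_mode = update_mode,
                 support_fraction = support_fraction, overlap = overlap,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Mean squared error loss
#'
#' Mean over the batch of the squared difference between predicted
#' probabilities and 0/1 targets.
#'
#' @param predictions Numeric vector of predictions.
#' @param targets Numeric vector of the same length.
#' @return Scalar loss.
#' @export
mse_loss <- function(predictions, targets) {
  if (length(predictions) == 0) stop("empty batch")
  if (length(predictions) != length(targets))
    stop("predictions and targets differ in length")
  mean((predictions - targets)^2)
}

#' Fresh moment state for a parameter set
#'
#' First and second gradient moments, zero-initialized with the shapes of
#' `params`, plus the step counter `o = 0`.
#'
#' @param params Named list of numeric parameter arrays.
#' @return A `moment_state` object with elements `m`, `v`, `o`.
#' @export
moment_state <- function(params) {
  structure(list(m = lapply(params, function(p) p * 0),
                 v = lapply(params, function(p) p * 0),
                 o = 0L),
            class = "moment_state")
}

#' One moment update
#'
#' `m <- phi1 * m + (1 - phi1) * g` and `v <- phi2 * v + (1 - phi2) * g^2`
#' elementwise; the step counter is incremented.
#'
#' @param state A [moment_state()].
#' @param gradients Named list shape-compatible with the state.
#' @param phi1,phi2 Exponential decay rates.
#' @return Updated `moment_state`.
#' @export
moment_update <- function(state, gradients, phi1 = 0.9, phi2 = 0.999) {
  stopifnot(inherits(state, "moment_state"))
  if (!identical(names(state$m), names(gradients)) ||
      !all(mapply(function(a, b) length(a) == length(b), state$m, gradients)))
    stop("gradient shapes do not match the moment state")
  upd <- Map(function(m, v, g) cpp_moment_update(m, v, g, phi1, phi2),
             state$m, state$v, gradients)
  state$m <- lapply(upd, `[[`, "m")
  state$v <- lapply(upd, `[[`, "v")
  state$o <- state$o + 1L
  state
}

.apply_update_core <- function(params, state, lr, mode, epsilon,
                               correct = TRUE, phi1 = 0.9, phi2 = 0.999) {
  correct <- correct && mode == "adam" && state$o > 0L
  c1 <- if (correct) 1 - phi1^state$o else 1
  c2 <- if (correct) 1 - phi2^state$o else 1
  Map(function(p, m, v) cpp_apply_step(p, m, v, lr, c1, c2, epsilon,
                                       mode == "literal"),
      params, state$m, state$v)
}

#' Apply one moment-based parameter update
#'
#' Subtracts a moment-based step from every parameter. In `"adam"` mode the
#' step is canonical Adam, `lr * mhat / (sqrt(vhat) + epsilon)` with the
#' bias-corrected moments `mhat = m / (1 - phi1^o)`,
#' `vhat = v / (1 - phi2^o)`; setting `correct = FALSE` uses the raw moments
#' `lr * m / (sqrt(v) + epsilon)`. In `"literal"` mode the step is
#' `lr * m / (epsilon + v)` — the recursion exactly as printed, with no
#' square root — which is numerically explosive for small gradients and is
#' provided for comparison. Applied stepwise along the training trajectory,
#' the per-episode sum of these steps telescopes into the episode's total
#' parameter change.
#'
#' @param params Named list of parameter arrays.
#' @param state The current [moment_state()].
#' @param lr Positive learning rate.
#' @param mode `"adam"` or `"literal"`.
#' @param epsilon Stability constant.
#' @param correct Apply Adam's bias correction (default `TRUE`; ignored in
#'   literal mode).
#' @param phi1,phi2 Decay rates used for the bias correction; must match
#'   those used in [moment_update()].
#' @return Updated parameter list.
#' @export
apply_update <- function(params, state, lr, mode = c("adam", "literal"),
                         epsilon = 1e-8, correct = TRUE,
                         phi1 = 0.9, phi2 = 0.999) {
  mode <- match.arg(mode)
  if (!is.numeric(lr) || lr <= 0) stop("learning rate must be positive")
  stopifnot(inherits(state, "moment_state"))
  .apply_update_core(params, state, lr, mode, epsilon, correct, phi1, phi2)
}

# ---- batching --------------------------------------------------------------

#' Assemble a minibatch in a model's native input format
#'
#' @param model Model object (dispatch).
#' @param data List with `x` (inputs) and `y` (0/1 labels).
#' @param idx Integer indices of the samples to include.
#' @param train Logical; training-mode preparation (augmentation).
#' @return List with `x` (batch) and `y` (labels).
#' @export
prepare_batch <- function(model, data, idx, train = TRUE)
  UseMethod("prepare_batch")

#' @export
prepare_batch.default <- function(model, data, idx, train = TRUE) {
  list(x = data$x[, idx, drop = FALSE], y = data$y[idx])
}

#' @export
prepare_batch.hybrid_model <- function(model, data, idx, train = TRUE) {
  cfg <- model$transform
  if (is.null(cfg)) stop("hybrid model has no transform configuration")
  side <- cfg$crop_side
  tens <- lapply(data$x[idx], function(img) {
    if (train) {
      cfg$mode <- "train"
      train_transform(img, cfg)
    } else {
      cfg$mode <- "eval"
      eval_transform(img, cfg)
    }
  })
  list(x = array(unlist(tens, use.names = FALSE),
                 c(side, side, 3, length(idx))),
       y = data$y[idx])
}

# ---- episodes --------------------------------------------------------------

validate_dataset <- function(data) {
  n <- if (is.list(data$x)) length(data$x) else ncol(data$x)
  if (is.null(n) || n == 0) stop("dataset is empty")
  if (length(data$y) != n) stop("inputs and labels differ in length")
  n
}

#' Run one training episode
#'
#' Performs `steps` minibatch gradient updates on `data` starting from fresh
#' moments: at each step a minibatch is drawn (without replacement,
#' reshuffling once an epoch is exhausted), the mean-squared-error loss and
#' gradients are computed, the moments are updated, and the moment-based
#' step is subtracted from the parameters. Deterministic under `seed`.
#'
#' @param model Model object implementing [model_gradients()].
#' @param data List with `x` and `y` (non-empty).
#' @param cfg A [train_config()].
#' @param steps Number of gradient updates (default `cfg$inner_steps`).
#' @param lr Learning rate (default `cfg$inner_lr`).
#' @param seed Optional integer; when given, the episode runs under its own
#'   derived RNG stream.
#' @return List with `model` (updated), `state` (final [moment_state()]) and
#'   `losses` (per-step minibatch losses).
#' @export
run_episode <- function(model, data, cfg, steps = cfg$inner_steps,
                        lr = cfg$inner_lr, seed = NULL) {
  n <- validate_dataset(data)
  if (steps < 1) stop("an episode needs at least one gradient update")
  body <- function() {
    state <- moment_state(model$params)
    losses <- numeric(steps)
    pool <- sample.int(n)
    pos <- 1L
    for (s in seq_len(steps)) {
      bsz <- min(cfg$batch_size, n)
      if (pos + bsz - 1L > n) { pool <- sample.int(n); pos <- 1L }
      idx <- pool[pos:(pos + bsz - 1L)]
      pos <- pos + bsz
      batch <- prepare_batch(model, data, idx, train = TRUE)
      g <- model_gradients(model, batch$x, batch$y)
      model <- g$model
      state <- moment_update(state, g$grads, cfg$phi1, cfg$phi2)
      if (lr > 0)
        model$params <- .apply_update_core(model$params, state, lr,
                                           cfg$update_mode, cfg$epsilon,
                                           TRUE, cfg$phi1, cfg$phi2)
      losses[s] <- g$loss
    }
    list(model = model, state = state, losses = losses)
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' Construct a per-device meta-task
#'
#' @param device Device name.
#' @param support,query Lists with `x` and `y`; both non-empty, drawn from
#'   the same device.
#' @return A `meta_task` object.
#' @export
meta_task <- function(device, support, query) {
  validate_dataset(support)
  validate_dataset(query)
  structure(list(device = device, support = support, query = query),
            class = "meta_task")
}

#' Split one device's data into support and query sets
#'
#' Random split by `fraction` (support side), optionally sharing
#' `overlap` of the support samples with the query set — the two sets need
#' not be disjoint.
#'
#' @param x List (images) or matrix (features, columns are samples).
#' @param y 0/1 labels.
#' @param fraction Support fraction in (0, 1).
#' @param overlap Fraction of support samples also added to the query set.
#' @param seed Integer seed.
#' @return List with `support` and `query` datasets.
#' @export
split_support_query <- function(x, y, fraction = 0.5, overlap = 0, seed = 1) {
  n <- if (is.list(x)) length(x) else ncol(x)
  stopifnot(n >= 2, fraction > 0, fraction < 1)
  take <- function(idx) {
    if (is.list(x)) list(x = x[idx], y = y[idx])
    else list(x = x[, idx, drop = FALSE], y = y[idx])
  }
  with_seed(seed, {
    perm <- sample.int(n)
    nsup <- max(1L, min(n - 1L, as.integer(round(fraction * n))))
    sup <- perm[seq_len(nsup)]
    que <- perm[(nsup + 1L):n]
    if (overlap > 0) {
      extra <- sup[seq_len(ceiling(overlap * nsup))]
      que <- c(que, extra)
    }
    list(support = take(sup), query = take(que))
  })
}

#' Episodic meta-training across devices
#'
#' Visits the tasks in order. For task `i`, one episode is run on the
#' support set starting from the parameters left by task `i - 1`'s query
#' episode (the very first support episode starts from the initial model),
#' then one episode on the query set starting from the support result.
#' Moments are reset at every episode boundary. Returns the model after the
#' last query episode, with the per-episode loss history attached as
#' attribute `"history"`.
#'
#' @param model Initial model.
#' @param tasks Ordered list of [meta_task()] objects (non-empty).
#' @param cfg A [train_config()].
#' @return The meta-trained model.
#' @export
meta_train <- function(model, tasks, cfg) {
  if (length(tasks) < 1) stop("meta_train needs at least one task")
  history <- list()
  for (i in seq_along(tasks)) {
    task <- tasks[[i]]
    stopifnot(inherits(task, "meta_task"))
    e1 <- run_episode(model, task$support, cfg,
                      seed = derive_seed(cfg$seed, sprintf("sup%d", i)))
    model <- e1$model
    e2 <- run_episode(model, task$query, cfg,
                      seed = derive_seed(cfg$seed, sprintf("que%d", i)))
    model <- e2$model
    history[[length(history) + 1L]] <- data.frame(
      task = i, device = task$device, phase = c("support", "query"),
      first_loss = c(e1$losses[1], e2$losses[1]),
      last_loss = c(e1$losses[cfg$inner_steps], e2$losses[cfg$inner_steps]),
      mean_loss = c(mean(e1$losses), mean(e2$losses)))
  }
  attr(model, "history") <- do.call(rbind, history)
  model
}

#' Fine-tune on data from an unseen device
#'
#' `cfg$finetune_steps` gradient updates at the fine-tuning learning rate,
#' starting from fresh moments, with the same moment-based update rule as
#' meta-training.
#'
#' @param model A (typically meta-trained) model.
#' @param data Non-empty adaptation set (`x`, `y`) from the new device.
#' @param cfg A [train_config()].
#' @return The adapted model (attribute `"finetune_losses"`).
#' @export
fine_tune <- function(model, data, cfg) {
  validate_dataset(data)
  if (cfg$finetune_steps < 1) stop("fine-tuning needs at least one step")
  e <- run_episode(model, data, cfg, steps = cfg$finetune_steps,
                   lr = cfg$finetune_lr,
                   seed = derive_seed(cfg$seed, "finetune"))
  m <- e$model
  attr(m, "history") <- attr(model, "history")
  attr(m, "finetune_losses") <- e$losses
  m
}
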