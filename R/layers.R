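# Internal layer primitives. Activation batches are (H, W, C, N) arrays;
# fully connected activations are (features, N) matrices. Every forward has a
# matching hand-derived backward; gradient correctness is checked against
# finite differences in the test suite.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# --- batch normalization over (H, W, N) per channel ------------------------
# Training statistics and the backward pass run in C++ (cpp_bn2d_*); the
# variance is the biased (population) estimate, the running variance is
# stored unbiased.
bn2d_forward <- function(x, g, b, rm, rv, training) {
  if (training) {
    d <- dim(x)
    m <- d[1] * d[2] * d[4]
    r <- cpp_bn2d_train(x, g, b)
    unb <- if (m > 1) m / (m - 1) else 1
    list(y = r$y,
         cache = list(xhat = r$xhat, istd = r$istd, dims = d),
         rm = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * r$mu,
         rv = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * r$var * unb)
  } else {
    a <- g / sqrt(rv + BN_EPS)
    list(y = cpp_scale_channels(x, a, b - rm * a), cache = NULL,
         rm = rm, rv = rv)
  }
}

bn2d_backward <- function(dy, g, cache) {
  r <- cpp_bn2d_train_backward(dy, cache$xhat, cache$istd, g)
  list(dx = r$dx, dg = as.numeric(r$dg), db = as.numeric(r$db))
}

# --- batch normalization over the batch per feature (x is features x N) ----
bn1d_forward <- function(x, g, b, rm, rv, training) {
  if (training) {
    n <- ncol(x)
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * istd
    unb <- if (n > 1) n / (n - 1) else 1
    list(y = xhat * g + b, cache = list(xhat = xhat, istd = istd),
         rm = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu,
         rv = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * v * unb)
  } else {
    a <- g / sqrt(rv + BN_EPS)
    list(y = x * a + (b - rm * a), cache = NULL, rm = rm, rv = rv)
  }
}

bn1d_backward <- function(dy, g, cache) {
  xhat <- cache$xhat
  dg <- rowSums(dy * xhat)
  db <- rowSums(dy)
  dxhat <- dy * g
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$istd
  list(dx = dx, dg = dg, db = db)
}

# --- activations -----------------------------------------------------------
relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

prelu_forward <- function(x, a) {
  pos <- x > 0
  list(y = x * pos + a * (x * !pos), pos = pos)
}

prelu_backward <- function(dy, x, a, pos) {
  list(dx = dy * (pos + a * !pos), da = sum(dy * (x * !pos)))
}

# --- dropout (inverted scaling; uses the ambient RNG stream) ---------------
dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  list(y = x * mask, mask = mask)
}

# --- fully connected -------------------------------------------------------
fc_forward <- function(x, w, b) w %*% x + b

fc_backward <- function(dy, x, w) {
  list(dx = crossprod(w, dy), dw = tcrossprod(dy, x), db = rowSums(dy))
}

# --- global average pooling (H,W,C,N) -> (C,N) -----------------------------
gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4])
}

gap_backward <- function(dy, dims) {
  sp <- dims[1] * dims[2]
  array(rep(as.numeric(dy) / sp, each = sp), dims)
}
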