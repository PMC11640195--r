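#' Transform configuration
#'
#' Describes the input preparation feeding the classifier: resize to
#' `resize_side` x `resize_side`, an optional horizontal flip (training
#' only), a `crop_side` x `crop_side` window (uniform-random in training,
#' centered in evaluation), then per-image standardization.
#'
#' @param resize_side Resize target in pixels (default 256).
#' @param crop_side Crop size in pixels (default 224, must not exceed
#'   `resize_side`).
#' @param hflip_prob Probability of a horizontal flip in training mode.
#' @param mode `"train"` or `"eval"`.
#' @param seed Base seed for index-derived augmentation streams.
#' @param channelwise Standardize each colour channel separately (default)
#'   or with one mean and standard deviation over all pixels.
#' @return A `transform_config` object.
#' @export
transform_config <- function(resize_side = 256, crop_side = 224,
                             hflip_prob = 0.5, mode = c("train", "eval"),
                             seed = 0, channelwise = TRUE) {
  mode <- match.arg(mode)
  stopifnot(crop_side <= resize_side, crop_side >= 1,
            hflip_prob >= 0, hflip_prob <= 1)
  structure(list(resize_side = as.integer(resize_side),
                 crop_side = as.integer(crop_side),
                 hflip_prob = hflip_prob, mode = mode,
                 seed = as.integer(seed), channelwise = channelwise),
            class = "transform_config")
}

#' Per-image standardization
#'
#' Centers and scales pixel values to zero mean and unit standard deviation
#' using the population statistics of this image: `(x - mu) / sigma` with
#' `mu` and `sigma` computed over all `w x h` pixels, per channel by default.
#' A constant channel (zero standard deviation) carries no signal and is
#' returned as all zeros with a warning.
#'
#' @param image Numeric array `(H, W, C)` or matrix.
#' @param channelwise Per-channel statistics (default) or joint over all
#'   pixels.
#' @return Standardized array of the same shape.
#' @export
standardize_image <- function(image, channelwise = TRUE) {
  if (length(image) == 0) stop("empty image")
  std1 <- function(x, what) {
    mu <- mean(x)
    s <- sqrt(mean((x - mu)^2))
    if (s == 0) {
      warning(sprintf("constant %s: standardized to zeros", what))
      return(x * 0)
    }
    (x - mu) / s
  }
  d <- dim(image)
  if (!is.null(d) && length(d) == 3 && channelwise) {
    out <- image
    for (c3 in seq_len(d[3]))
      out[, , c3] <- std1(image[, , c3], sprintf("channel %d", c3))
    out
  } else {
    std1(image, "image")
  }
}

flip_horizontal <- function(image) {
  d <- dim(image)
  if (length(d) == 3) image[, rev(seq_len(d[2])), , drop = FALSE]
  else image[, rev(seq_len(d[2])), drop = FALSE]
}

#' Stochastic training transform
#'
#' Resize to `resize_side`, horizontal flip with probability `hflip_prob`,
#' uniform-random `crop_side` crop, standardize. When `index` is supplied
#' the augmentation draws come from a stream derived from
#' `(cfg$seed, index)`, making the result reproducible per image;
#' otherwise the ambient RNG stream is used (one flip draw, then two offset
#' draws).
#'
#' @param image RGB array `(H, W, 3)`.
#' @param cfg A [transform_config()] with `mode = "train"`.
#' @param index Optional integer identifying the image/draw.
#' @return Standardized `(crop_side, crop_side, 3)` array.
#' @export
train_transform <- function(image, cfg, index = NULL) {
  stopifnot(inherits(cfg, "transform_config"))
  if (cfg$mode != "train") stop("cfg$mode must be 'train'")
  body <- function() {
    r <- cpp_resize_bilinear(image, cfg$resize_side, cfg$resize_side)
    if (cfg$hflip_prob > 0 && runif(1) < cfg$hflip_prob)
      r <- flip_horizontal(r)
    span <- cfg$resize_side - cfg$crop_side + 1L
    oy <- sample.int(span, 1L) - 1L
    ox <- sample.int(span, 1L) - 1L
    r <- r[oy + seq_len(cfg$crop_side), ox + seq_len(cfg$crop_side), ,
           drop = FALSE]
    standardize_image(r, cfg$channelwise)
  }
  if (is.null(index)) body()
  else with_seed(derive_seed(cfg$seed, paste0("aug", index)), body())
}

#' Deterministic evaluation transform
#'
#' Resize to `resize_side`, center crop `crop_side` (offset
#' `floor((resize_side - crop_side) / 2)` on both axes), standardize.
#'
#' @param image RGB array `(H, W, 3)`.
#' @param cfg A [transform_config()] with `mode = "eval"`.
#' @return Standardized `(crop_side, crop_side, 3)` array.
#' @export
eval_transform <- function(image, cfg) {
  stopifnot(inherits(cfg, "transform_config"))
  if (cfg$mode != "eval") stop("cfg$mode must be 'eval'")
  r <- cpp_resize_bilinear(image, cfg$resize_side, cfg$resize_side)
  off <- (cfg$resize_side - cfg$crop_side) %/% 2L
  r <- r[off + seq_len(cfg$crop_side), off + seq_len(cfg$crop_side), ,
         drop = FALSE]
  standardize_image(r, cfg$channelwise)
}
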