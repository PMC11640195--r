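`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a child random seed from a parent seed and a key
#'
#' All stochastic stages derive their own seed from one global integer seed so
#' that results are reproducible regardless of the order in which stages run.
#' Strings are hashed with a 31-ary polynomial; everything is kept below
#' 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed Integer parent seed.
#' @param key Scalar (string or number) identifying the consumer stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% m
  }
  as.integer((h * 69069 + 12345) %% m)
}

# Run code under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
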