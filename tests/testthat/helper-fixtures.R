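# Shared helpers: small scenes/profiles render in well under a second, and
# the expensive easy-preset artifacts used by the acceptance suite are built
# once and memoized for the whole test run.

small_scene <- function(...) {
  scene_spec(width = 96, height = 72, ...)
}

small_profile <- function(name = "tst", w = 80, h = 60, ...) {
  device_profile(name, w, h, ...)
}

identity_profile <- function(w, h) {
  device_profile("id", w, h, color_temp_shift = 0, saturation_scale = 1,
                 gamma = 1, noise_sd = 0)
}

# Renders a blob-only image with a known mask for oracle comparisons.
blob_image <- function(seed = 1, include_ruler = FALSE, label = 1) {
  app <- builtin_class_appearances(1)[[if (label == 1) "HS" else "NS"]]
  render_scene(small_scene(include_ruler = include_ruler), app, seed = seed)
}

# Independent scalar reimplementation of the moment recursion and both
# update rules, used as the optimizer oracle.
oracle_moments <- function(grads, phi1 = 0.9, phi2 = 0.999) {
  m <- 0; v <- 0
  ms <- numeric(length(grads)); vs <- numeric(length(grads))
  for (i in seq_along(grads)) {
    m <- phi1 * m + (1 - phi1) * grads[i]
    v <- phi2 * v + (1 - phi2) * grads[i]^2
    ms[i] <- m; vs[i] <- v
  }
  list(m = ms, v = vs)
}

oracle_step <- function(m, v, o, lr, mode, eps = 1e-8, correct = TRUE,
                        phi1 = 0.9, phi2 = 0.999) {
  if (mode == "literal") return(lr * m / (eps + v))
  if (!correct) return(lr * m / (sqrt(v) + eps))
  lr * (m / (1 - phi1^o)) / (sqrt(v / (1 - phi2^o)) + eps)
}

# Lazily built, memoized easy-preset artifacts for the acceptance tests.
.acc_cache <- new.env(parent = emptyenv())

easy_crops <- function() {
  if (is.null(.acc_cache$man)) {
    out <- file.path(tempdir(), "acc_easy")
    profiles <- builtin_device_profiles(1 / 16)
    scene <- scene_spec(width = 256L, height = 192L)
    man <- generate_dataset(profiles, c(HS = 66, NS = 68), file.path(out, "img"),
                            seed = derive_seed(1, "simulate"),
                            scene = scene)
    cman <- crop_dataset(man, file.path(out, "img"), file.path(out, "crops"),
                         frame_short_side = 128)
    .acc_cache$man <- cman
    .acc_cache$images <- load_images(cman, dir = file.path(out, "crops"),
                                     resize_to = 72)
  }
  list(manifest = .acc_cache$man, images = .acc_cache$images)
}
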