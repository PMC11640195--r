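#' Camera device profile
#'
#' A simulated phone camera. Device shift is modelled as a fixed colour
#' transform plus sensor noise: channel-balance shift (warm/cool), saturation
#' scaling, gamma, additive Gaussian noise, and the device's native output
#' resolution.
#'
#' @param name Short device identifier, e.g. `"iPh"`.
#' @param width,height Output resolution in pixels.
#' @param color_temp_shift Signed fraction applied to the R/B channel balance
#'   (`R * (1 + s)`, `B * (1 - s)`); positive is warmer.
#' @param saturation_scale Multiplicative saturation factor, `>= 0`.
#' @param gamma Tone-curve exponent, `> 0`.
#' @param noise_sd Additive Gaussian sensor noise standard deviation in
#'   `[0, 1]` intensity units.
#' @return A `device_profile` object.
#' @export
device_profile <- function(name, width, height, color_temp_shift = 0,
                           saturation_scale = 1, gamma = 1, noise_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (nm in c("width", "height", "color_temp_shift", "saturation_scale",
               "gamma", "noise_sd"))
    stopifnot_scalar(get(nm), nm)
  if (width < 1 || height < 1) stop("profile resolution must be positive")
  if (gamma <= 0) stop("gamma must be > 0")
  if (saturation_scale < 0) stop("saturation_scale must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(name = name, width = as.integer(round(width)),
                 height = as.integer(round(height)),
                 color_temp_shift = color_temp_shift,
                 saturation_scale = saturation_scale, gamma = gamma,
                 noise_sd = noise_sd),
            class = "device_profile")
}

#' Built-in device profiles
#'
#' The four phone profiles used throughout: `iPh` (4032 x 3024), `Vo`
#' (4080 x 3060), `Ho` (4608 x 3056) and `Mi` (4032 x 3016). The colour
#' parameters are fixed package choices emulating cross-device differences in
#' chroma, saturation and tone; `Ho` is the conventional held-out device.
#'
#' @param resolution_scale Factor applied to the native resolutions (keeps
#'   aspect ratio; useful for fast reduced-resolution experiments).
#' @return Named list of [device_profile()] objects.
#' @export
builtin_device_profiles <- function(resolution_scale = 1) {
  stopifnot(resolution_scale > 0)
  sc <- function(x) max(1L, as.integer(round(x * resolution_scale)))
  list(
    iPh = device_profile("iPh", sc(4032), sc(3024),  0.04, 1.10, 0.95, 0.012),
    Vo  = device_profile("Vo",  sc(4080), sc(3060), -0.03, 0.92, 1.05, 0.018),
    Ho  = device_profile("Ho",  sc(4608), sc(3056), -0.05, 1.15, 0.90, 0.020),
    Mi  = device_profile("Mi",  sc(4032), sc(3016),  0.02, 0.85, 1.10, 0.025)
  )
}

#' Class appearance parameters
#'
#' Controls how a class (sulfur-fumigated vs untreated) renders: base hue of
#' the rhizome surface, brightness offset, and texture contrast (surface
#' roughness amplitude; it also drives the texture's spatial frequency).
#'
#' @param label Class label, 0 (non-fumigated, NS) or 1 (fumigated, HS).
#' @param base_hue Hue in degrees.
#' @param brightness_offset Signed fraction added to the surface value.
#' @param texture_contrast Roughness amplitude in `[0, 1]`.
#' @return A `class_appearance` object.
#' @export
class_appearance <- function(label, base_hue, brightness_offset,
                             texture_contrast) {
  stopifnot(label %in% c(0, 1), texture_contrast >= 0, texture_contrast <= 1)
  structure(list(label = as.integer(label), base_hue = base_hue,
                 brightness_offset = brightness_offset,
                 texture_contrast = texture_contrast),
            class = "class_appearance")
}

#' Built-in class appearances with a tunable effect size
#'
#' Sulfur fumigation bleaches and smooths the rhizome surface: the HS class is
#' rendered paler, brighter and smoother than NS. `effect` scales all three
#' differences from a common midpoint; `effect = 0` makes the classes
#' identical in expectation, `effect = 1` is the "easy separability" preset.
#'
#' @param effect Non-negative class effect size.
#' @return List with elements `NS` (label 0) and `HS` (label 1).
#' @export
builtin_class_appearances <- function(effect = 1) {
  stopifnot(effect >= 0)
  mid_hue <- 42; mid_bright <- 0.02; mid_tex <- 0.28
  list(
    NS = class_appearance(0, mid_hue - 10 * effect,
                          mid_bright - 0.08 * effect,
                          min(1, mid_tex + 0.17 * effect)),
    HS = class_appearance(1, mid_hue + 10 * effect,
                          mid_bright + 0.08 * effect,
                          max(0.02, mid_tex - 0.17 * effect))
  )
}

#' Scene specification for rendered specimens
#'
#' One photograph: a near-white background, one ginger-like blob (a union of
#' overlapping ellipses) and optionally a ruler-like elongated distractor
#' whose footprint is strictly smaller than the blob's, so largest-region
#' selection always picks the specimen.
#'
#' @param width,height Render resolution in pixels.
#' @param background_intensity Background level (near-white fraction).
#' @param blob_center Blob centre as fractions of (width, height).
#' @param blob_radius Primary semi-axis as a fraction of `min(width, height)`.
#' @param n_lobes Number of overlapping ellipses forming the blob.
#' @param include_ruler Whether to draw the ruler distractor.
#' @param ruler_area_fraction Ruler footprint as a fraction of the frame
#'   area; must stay below the approximate blob area fraction.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(width = 1024, height = 768,
                       background_intensity = 0.94,
                       blob_center = c(0.5, 0.48), blob_radius = 0.27,
                       n_lobes = 3, include_ruler = TRUE,
                       ruler_area_fraction = 0.035) {
  stopifnot(width >= 16, height >= 16, n_lobes >= 1,
            background_intensity > 0, background_intensity <= 1)
  if (blob_radius <= 0) stop("degenerate footprint: blob_radius must be > 0")
  blob_area_approx <- pi * blob_radius^2 * 0.6 *
    min(width, height)^2 / (width * height)
  if (include_ruler && ruler_area_fraction >= blob_area_approx)
    stop("ruler footprint must be smaller than the specimen footprint")
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_intensity = background_intensity,
                 blob_center = blob_center, blob_radius = blob_radius,
                 n_lobes = as.integer(n_lobes), include_ruler = include_ruler,
                 ruler_area_fraction = ruler_area_fraction),
            class = "scene_spec")
}

#' Render a synthetic specimen photograph
#'
#' Deterministic given `(spec, appearance, seed)`. Returns an `(H, W, 3)`
#' array in `[0, 1]` at the scene's working resolution, with the specimen
#' pixel mask attached as attribute `"mask"` (and `"ruler_mask"` when a ruler
#' is drawn).
#'
#' @param spec A [scene_spec()].
#' @param appearance A [class_appearance()].
#' @param seed Integer seed for the per-image jitter and texture.
#' @return RGB array `(height, width, 3)` with attributes `mask` and
#'   `ruler_mask` (logical matrices).
#' @export
render_scene <- function(spec, appearance, seed = 1) {
  stopifnot(inherits(spec, "scene_spec"), inherits(appearance, "class_appearance"))
  H <- spec$height; W <- spec$width
  with_seed(seed, {
    X <- matrix(seq_len(W), H, W, byrow = TRUE)
    Y <- matrix(seq_len(H), H, W)
    mask <- matrix(FALSE, H, W)
    r0 <- spec$blob_radius * min(W, H)
    for (i in seq_len(spec$n_lobes)) {
      cx <- (spec$blob_center[1] + runif(1, -0.05, 0.05)) * W
      cy <- (spec$blob_center[2] + runif(1, -0.04, 0.04)) * H
      a <- r0 * runif(1, 0.8, 1.05)
      b <- a * runif(1, 0.55, 0.8)
      th <- runif(1, 0, pi)
      dx <- X - cx; dy <- Y - cy
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      mask <- mask | (u * u + v * v <= 1)
    }
    if (!any(mask)) stop("degenerate footprint: specimen has zero area")

    base <- grDevices::col2rgb(grDevices::hsv(
      (appearance$base_hue / 360) %% 1, 0.55,
      clamp01(0.62 + appearance$brightness_offset)))[, 1] / 255

    # Surface texture: oriented waves plus pixel grain; amplitude and spatial
    # frequency both grow with texture_contrast (rough NS vs smooth HS).
    tc <- appearance$texture_contrast
    freq <- (6 + 30 * tc) / min(W, H)
    waves <- 0
    amp <- c(0.5, 0.3, 0.2)
    for (s in 1:3) {
      ang <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
      f <- freq * runif(1, 0.7, 1.4)
      waves <- waves + amp[s] *
        sin(2 * pi * f * (cos(ang) * X + sin(ang) * Y) + ph)
    }
    grain <- matrix(rnorm(H * W), H, W)
    texture <- 1 + tc * (0.6 * waves + 0.45 * grain)

    bg <- spec$background_intensity + 0.02 * (Y / H - 0.5)
    img <- array(0, c(H, W, 3))
    for (c3 in 1:3) {
      ch <- bg
      ch[mask] <- base[c3] * texture[mask]
      img[, , c3] <- ch
    }

    ruler_mask <- matrix(FALSE, H, W)
    if (spec$include_ruler) {
      rw <- round(0.55 * W)
      rh <- max(2L, as.integer(round(spec$ruler_area_fraction * W * H / rw)))
      x0 <- max(1L, as.integer(round(0.1 * W)))
      y1 <- H - max(1L, as.integer(round(0.05 * H)))
      y0 <- max(1L, y1 - rh + 1L)
      cols <- x0:min(W, x0 + rw - 1L)
      rows <- y0:y1
      ruler_mask[rows, cols] <- TRUE
      tick <- max(2L, as.integer(round(W / 80)))
      tickpat <- ((X - x0) %/% tick) %% 2
      for (c3 in 1:3) {
        ch <- img[, , c3]
        ch[ruler_mask] <- ifelse(tickpat[ruler_mask] == 0, 0.42, 0.62)
        img[, , c3] <- ch
      }
    }
    img <- clamp01(img)
    attr(img, "mask") <- mask
    attr(img, "ruler_mask") <- ruler_mask
    img
  })
}

#' Apply a camera device profile to an image
#'
#' Resamples the image to the profile's resolution, then applies the colour
#' transform in a fixed order: channel-balance shift, saturation scaling,
#' gamma, additive Gaussian sensor noise, and clipping to `[0, 1]`. The
#' identity profile (no shift, unit scale/gamma, zero noise, same resolution)
#' returns the input unchanged.
#'
#' @param image RGB array `(H, W, 3)` in `[0, 1]`.
#' @param profile A [device_profile()].
#' @param seed Integer seed for the sensor noise.
#' @return RGB array `(profile$height, profile$width, 3)`.
#' @export
apply_device_profile <- function(image, profile, seed = 1) {
  stopifnot(inherits(profile, "device_profile"), length(dim(image)) == 3)
  out <- image
  attributes(out) <- list(dim = dim(image))
  if (dim(out)[1] != profile$height || dim(out)[2] != profile$width)
    out <- cpp_resize_bilinear(out, profile$height, profile$width)
  s <- profile$color_temp_shift
  if (s != 0) {
    out[, , 1] <- out[, , 1] * (1 + s)
    out[, , 3] <- out[, , 3] * (1 - s)
  }
  if (profile$saturation_scale != 1) {
    luma <- 0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3]
    for (c3 in 1:3)
      out[, , c3] <- luma + profile$saturation_scale * (out[, , c3] - luma)
  }
  if (profile$gamma != 1)
    out <- pmax(out, 0)^profile$gamma
  if (profile$noise_sd > 0)
    out <- out + with_seed(seed, array(rnorm(length(out), sd = profile$noise_sd),
                                       dim(out)))
  out <- clamp01(out)
  dim(out) <- c(profile$height, profile$width, 3L)
  out
}

#' Generate a labelled synthetic dataset
#'
#' Renders `counts_per_class["HS"]` fumigated and `counts_per_class["NS"]`
#' untreated specimens for each device profile, writes the images and a
#' manifest CSV (`sample_id,path,device,label,width,height`) under `out_dir`,
#' and returns the manifest. Sample ids follow `<device>_<NS|HS>_<index>`
#' (e.g. `iPh_HS_01`). Every image's randomness derives from
#' `derive_seed(seed, sample_id)`, so the dataset is reproducible regardless
#' of generation order.
#'
#' @param profiles List of [device_profile()] objects.
#' @param counts_per_class Named vector/list with non-negative `HS` and `NS`
#'   counts per device.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param appearances List with `NS` and `HS` [class_appearance()] entries.
#' @param scene A [scene_spec()] giving the working render resolution.
#' @param format `"png"` (lossless, default) or `"jpeg"`.
#' @param invert_labels If `TRUE`, invert the label convention (HS becomes 0).
#' @return Manifest `data.frame`, invisibly carrying attribute
#'   `"manifest_path"`.
#' @export
generate_dataset <- function(profiles, counts_per_class = c(HS = 66, NS = 68),
                             out_dir, seed = 1,
                             appearances = builtin_class_appearances(),
                             scene = scene_spec(), format = c("png", "jpeg"),
                             invert_labels = FALSE) {
  format <- match.arg(format)
  counts <- as.list(counts_per_class)
  stopifnot(all(c("HS", "NS") %in% names(counts)),
            counts$HS >= 0, counts$NS >= 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  ext <- if (format == "png") ".png" else ".jpg"
  for (p in profiles) {
    for (cls in c("NS", "HS")) {
      app <- appearances[[cls]]
      n <- as.integer(counts[[cls]])
      lab <- if (cls == "HS") 1L else 0L
      if (invert_labels) lab <- 1L - lab
      for (i in seq_len(n)) {
        sid <- sprintf("%s_%s_%02d", p$name, cls, i)
        sseed <- derive_seed(seed, sid)
        img <- render_scene(scene, app, seed = sseed)
        img <- apply_device_profile(img, p, seed = derive_seed(sseed, "dev"))
        fn <- paste0(sid, ext)
        path <- file.path(out_dir, fn)
        if (format == "png") {
          png::writePNG(img, target = path)
        } else {
          EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)),
                                             colormode = "Color"),
                              path, quality = 95)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, path = fn, device = p$name, label = lab,
          width = dim(img)[2], height = dim(img)[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), path = character(),
               device = character(), label = integer(), width = integer(),
               height = integer(), stringsAsFactors = FALSE)
  mp <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  attr(manifest, "manifest_path") <- mp
  manifest
}
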