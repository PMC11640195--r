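#' Read an image file
#'
#' PNG via the png package, JPEG via EBImage; returned as an `(H, W, 3)`
#' array in `[0, 1]`.
#'
#' @param path Image file path.
#' @return RGB array.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    eb <- EBImage::readImage(path)
    img <- aperm(EBImage::imageData(eb), c(2, 1, 3))
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Read and validate a manifest CSV
#'
#' Requires the header `sample_id,path,device,label,width,height`, labels in
#' {0, 1}, non-empty device names, and (by default) that every referenced
#' image file exists relative to the manifest's directory. Problems are
#' reported with their row number.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify the image files exist.
#' @return Manifest `data.frame` with attribute `"dir"`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path", "device", "label", "width", "height")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!(m$label %in% c(0L, 1L)))
  if (length(bad))
    stop(sprintf("manifest row %d: label must be 0 or 1 (got %s)",
                 bad[1], m$label[bad[1]]))
  bad <- which(!nzchar(m$device))
  if (length(bad)) stop(sprintf("manifest row %d: empty device", bad[1]))
  dir <- dirname(path)
  if (check_files) {
    for (i in seq_len(nrow(m))) {
      f <- file.path(dir, m$path[i])
      if (!file.exists(f))
        stop(sprintf("manifest row %d: image file not found: %s", i, f))
    }
  }
  attr(m, "dir") <- dir
  m
}

#' Load the images of a manifest into memory
#'
#' @param manifest Manifest `data.frame`.
#' @param dir Directory the manifest paths are relative to (defaults to the
#'   manifest's own directory when available).
#' @param resize_to Optional side length; images are resampled to
#'   `resize_to x resize_to` on load to bound memory.
#' @return Named list of RGB arrays keyed by `sample_id`.
#' @export
load_images <- function(manifest, dir = NULL, resize_to = NULL) {
  dir <- dir %||% attr(manifest, "dir") %||%
    dirname(attr(manifest, "manifest_path") %||% ".")
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$sample_id
  for (i in seq_len(nrow(manifest))) {
    img <- load_image(file.path(dir, manifest$path[i]))
    if (!is.null(resize_to))
      img <- cpp_resize_bilinear(img, resize_to, resize_to)
    out[[i]] <- img
  }
  out
}

manifest_dataset <- function(manifest, images) {
  ids <- manifest$sample_id
  if (is.list(images)) list(x = images[ids], y = manifest$label)
  else list(x = images[, ids, drop = FALSE], y = manifest$label)
}

#' Per-repeat training/evaluation configuration
#'
#' The trainer behind [repeated_split_experiment()] and [ratio_sweep()]:
#' plain episodic training on the train side (`mode = "plain"`), the full
#' meta-train/fine-tune protocol (`mode = "meta"`, meta-training on the
#' train rows of the non-holdout devices and fine-tuning on the train rows
#' of the holdout device), or two frozen-backbone adaptation protocols
#' starting from a meta-trained `base_model`:
#'
#' * `mode = "head"` — each repeat recalibrates the backbone's
#'   normalization statistics on the train-side images, extracts backbone
#'   features, and trains the classifier head on them (with `epochs` set,
#'   recalibration depth and head steps scale with the adaptation set).
#' * `mode = "probe"` — the deterministic variant used by the scaled-down
#'   training-ratio sweep: one sequential evaluation-mode recalibration
#'   pass over the train side, feature standardization with train-side
#'   statistics, and a zero-initialized linear readout trained full-batch.
#'   Given the split, the result is a pure function of the data, so the
#'   repeat-to-repeat variation reflects the splits (the quantity under
#'   study) rather than optimization noise.
#'
#' @param mode `"plain"`, `"meta"`, `"head"` or `"probe"`.
#' @param transform A [transform_config()].
#' @param train A [train_config()].
#' @param bcfg,hcfg Model configurations.
#' @param holdout Held-out device name (meta mode).
#' @param threshold Decision threshold for evaluation.
#' @param steps Gradient steps for plain mode (defaults to
#'   `train$inner_steps`).
#' @param model_builder Optional `function(seed)` returning the model to
#'   train, overriding the hybrid-model construction (then `images` must be
#'   in that model's native input format).
#' @param base_model Meta-trained `hybrid_model` required by `mode = "head"`.
#' @param recal_batches Normalization-recalibration forward passes per
#'   training phase (`mode = "head"` without `epochs`).
#' @param epochs In `mode = "head"`, scale the head's gradient steps
#'   (`epochs` passes) and the recalibration depth (one pass) with the size
#'   of the adaptation set, instead of using fixed counts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("plain", "meta", "head", "probe"),
                            transform = transform_config(),
                            train = train_config(),
                            bcfg = backbone_config(),
                            hcfg = basenet_config(),
                            holdout = "Ho", threshold = 0.5,
                            steps = NULL, model_builder = NULL,
                            base_model = NULL, recal_batches = 8,
                            epochs = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("head", "probe") && is.null(base_model))
    stop(sprintf("mode = '%s' needs a meta-trained base_model", mode))
  structure(list(mode = mode, transform = transform, train = train,
                 bcfg = bcfg, hcfg = hcfg, holdout = holdout,
                 threshold = threshold,
                 steps = steps %||% train$inner_steps,
                 model_builder = model_builder, base_model = base_model,
                 recal_batches = recal_batches, epochs = epochs),
            class = "pipeline_config")
}

#' Train on one split and evaluate on the other
#'
#' @param train_manifest,test_manifest Disjoint manifest subsets.
#' @param images Named image list or feature matrix (columns by sample id).
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return A [compute_metrics()] report.
#' @export
train_and_evaluate <- function(train_manifest, test_manifest, images,
                               config, seed = 1) {
  tcfg0 <- config$train
  if (config$mode == "probe") {
    # calibration passes use evaluation-sized batches of 16 images
    base <- recalibrate_bn(config$base_model,
                           manifest_dataset(train_manifest, images),
                           batch_size = 16, deterministic = TRUE)
    both <- rbind(train_manifest, test_manifest)
    feats <- extract_features(base, images[both$sample_id], batch_size = 64)
    # standardize each feature with train-side statistics
    trf <- feats[, train_manifest$sample_id, drop = FALSE]
    mu <- rowMeans(trf)
    sdv <- apply(trf, 1, stats::sd)
    sdv[sdv == 0] <- 1
    feats <- (feats - mu) / sdv
    probe <- linear_classifier(nrow(feats), seed = 1, init_sd = 0)
    ep <- run_episode(probe, manifest_dataset(train_manifest, feats), tcfg0,
                      steps = config$steps, seed = derive_seed(seed, "ep"))
    return(evaluate_model(ep$model, manifest_dataset(test_manifest, feats),
                          threshold = config$threshold))
  }
  if (config$mode == "head") {
    # Frozen-backbone adaptation: recalibrate the backbone's normalization
    # statistics on the train side, extract features once, train the head.
    # With `epochs` set, both the recalibration depth and the number of head
    # steps scale with the adaptation set (one recalibration epoch,
    # `epochs` training epochs), so accuracy genuinely reflects how much
    # adaptation data is available.
    n <- nrow(train_manifest)
    bsz <- tcfg0$batch_size
    nb <- if (is.null(config$epochs)) config$recal_batches else
      max(1L, ceiling(n / bsz))
    steps <- if (is.null(config$epochs)) config$steps else
      max(1L, ceiling(config$epochs * n / bsz))
    tcfg0$seed <- derive_seed(seed, "t")
    base <- recalibrate_bn(config$base_model,
                           manifest_dataset(train_manifest, images),
                           batches = nb, seed = derive_seed(seed, "rc"))
    both <- rbind(train_manifest, test_manifest)
    feats <- extract_features(base, images[both$sample_id], batch_size = 64)
    head <- head_model(base)
    ep <- run_episode(head, manifest_dataset(train_manifest, feats), tcfg0,
                      steps = steps, seed = derive_seed(seed, "ep"))
    head <- recalibrate_bn(ep$model,
                           manifest_dataset(train_manifest, feats),
                           batches = nb, seed = derive_seed(seed, "rc2"))
    return(evaluate_model(head, manifest_dataset(test_manifest, feats),
                          threshold = config$threshold))
  }
  tcfg0$seed <- derive_seed(seed, "trainseed")
  model <- if (is.null(config$model_builder)) {
    build_hybrid_model(config$bcfg, config$hcfg,
                       seed = derive_seed(seed, "init"),
                       transform = config$transform)
  } else {
    config$model_builder(derive_seed(seed, "init"))
  }
  tcfg <- config$train
  tcfg$seed <- derive_seed(seed, "trainseed")
  if (config$mode == "plain") {
    ep <- run_episode(model, manifest_dataset(train_manifest, images), tcfg,
                      steps = config$steps,
                      seed = derive_seed(seed, "plain"))
    model <- ep$model
  } else {
    devs <- setdiff(unique(train_manifest$device), config$holdout)
    tasks <- lapply(devs, function(d) {
      rows <- train_manifest[train_manifest$device == d, , drop = FALSE]
      ds <- manifest_dataset(rows, images)
      sq <- split_support_query(ds$x, ds$y, fraction = tcfg$support_fraction,
                                overlap = tcfg$overlap,
                                seed = derive_seed(seed, paste0("task", d)))
      meta_task(d, sq$support, sq$query)
    })
    model <- meta_train(model, tasks, tcfg)
    hrows <- train_manifest[train_manifest$device == config$holdout, ,
                            drop = FALSE]
    if (nrow(hrows) > 0)
      model <- fine_tune(model, manifest_dataset(hrows, images), tcfg)
  }
  model <- recalibrate_bn(model, manifest_dataset(train_manifest, images),
                          seed = derive_seed(seed, "recal"))
  evaluate_model(model, manifest_dataset(test_manifest, images),
                 threshold = config$threshold)
}

#' End-to-end run configuration
#'
#' One nested configuration for the whole pipeline (simulate, crop,
#' meta-train, fine-tune, evaluate). Two presets are built in:
#' `"easy"` — the reduced-resolution, clearly separable synthetic study
#' (renders at 256 x 192, device resolutions scaled by 1/16, 64 x 64
#' network inputs); `"paper-scale"` — full native device resolutions and
#' 224 x 224 inputs (slow; intended for real photograph manifests).
#' Every stochastic stage derives its seed from the global `seed`.
#'
#' @param preset `"easy"` or `"paper-scale"`.
#' @param out_dir Output directory for images, crops, checkpoints, reports.
#' @param seed Global integer seed.
#' @param ... Named overrides merged into the preset (top-level keys:
#'   `fixtures`, `cropping`, `preprocess`, `model`, `metatrain`,
#'   `evaluation`).
#' @return A `run_config` object (nested list).
#' @export
run_config <- function(preset = c("easy", "paper-scale"),
                       out_dir = tempfile("gingershift_run_"), seed = 1,
                       ...) {
  preset <- match.arg(preset)
  base <- list(
    seed = as.integer(seed), out_dir = out_dir, preset = preset,
    fixtures = list(
      resolution_scale = if (preset == "easy") 1 / 16 else 1,
      scene = if (preset == "easy")
        list(width = 256L, height = 192L) else
          list(width = 1024L, height = 768L),
      effect = 1, counts = list(HS = 66L, NS = 68L), format = "png"),
    cropping = list(detector = "fallback",
                    frame_short_side = if (preset == "easy") 128L else 512L,
                    score_min = 0.5, area_min_fraction = 0.01),
    preprocess = list(
      resize_side = if (preset == "easy") 72L else 256L,
      crop_side = if (preset == "easy") 64L else 224L,
      hflip_prob = 0.5, channelwise = TRUE),
    model = list(pool_type = "average", dropout_p = 0.5),
    metatrain = list(inner_lr = 0.01, finetune_lr = 0.001,
                     phi1 = 0.9, phi2 = 0.999, epsilon = 1e-8,
                     inner_steps = 10L, finetune_steps = 50L,
                     batch_size = 16L, update_mode = "adam",
                     support_fraction = 0.5, overlap = 0),
    evaluation = list(train_devices = c("iPh", "Vo", "Mi"), holdout = "Ho",
                      adapt_fraction = 0.2, threshold = 0.5))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  structure(base, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the restored `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Run the whole pipeline end to end
#'
#' Simulate the device-shift dataset, crop every image, meta-train across
#' the training devices, fine-tune on a fraction of the held-out device,
#' and evaluate on that device's remaining images. All artifacts (images,
#' crops, resolved configuration, checkpoint, JSON report) are written
#' under `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress.
#' @return A `gingershift_run`: list with `report` (held-out device
#'   metrics), `model`, `manifest`, `timings`, `config`.
#' @export
run_end_to_end <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  t_all <- proc.time()[3]
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  seed <- cfg$seed
  timings <- c()
  tic <- function() proc.time()[3]
  lap <- function(t0, nm) {
    timings[nm] <<- round(proc.time()[3] - t0, 2)
  }

  t0 <- tic()
  say("[simulate] rendering synthetic dataset (seed %d)", seed)
  profiles <- builtin_device_profiles(cfg$fixtures$resolution_scale)
  appearances <- builtin_class_appearances(cfg$fixtures$effect)
  scene <- do.call(scene_spec, cfg$fixtures$scene)
  man <- generate_dataset(profiles,
                          counts_per_class = cfg$fixtures$counts,
                          out_dir = file.path(cfg$out_dir, "images"),
                          seed = derive_seed(seed, "simulate"),
                          appearances = appearances, scene = scene,
                          format = cfg$fixtures$format)
  lap(t0, "simulate")

  t0 <- tic()
  say("[crop] cropping %d images", nrow(man))
  cman <- crop_dataset(man, file.path(cfg$out_dir, "images"),
                       file.path(cfg$out_dir, "crops"),
                       detector = cfg$cropping$detector,
                       frame_short_side = cfg$cropping$frame_short_side,
                       score_min = cfg$cropping$score_min,
                       area_min_fraction = cfg$cropping$area_min_fraction)
  lap(t0, "crop")

  t0 <- tic()
  images <- load_images(cman, dir = file.path(cfg$out_dir, "crops"),
                        resize_to = cfg$preprocess$resize_side)
  tcfg <- transform_config(resize_side = cfg$preprocess$resize_side,
                           crop_side = cfg$preprocess$crop_side,
                           hflip_prob = cfg$preprocess$hflip_prob,
                           mode = "train",
                           seed = derive_seed(seed, "augment"),
                           channelwise = cfg$preprocess$channelwise)
  model <- build_hybrid_model(
    backbone_config(pool_type = cfg$model$pool_type),
    basenet_config(dropout_p = cfg$model$dropout_p),
    seed = derive_seed(seed, "init"), transform = tcfg)
  mcfg <- do.call(train_config,
                  c(cfg$metatrain, list(seed = derive_seed(seed, "episodes"))))
  tasks <- lapply(cfg$evaluation$train_devices, function(d) {
    rows <- cman[cman$device == d, , drop = FALSE]
    if (nrow(rows) == 0) stop("no images for training device ", d)
    ds <- manifest_dataset(rows, images)
    sq <- split_support_query(ds$x, ds$y, fraction = mcfg$support_fraction,
                              overlap = mcfg$overlap,
                              seed = derive_seed(seed, paste0("task", d)))
    meta_task(d, sq$support, sq$query)
  })
  say("[meta-train] %d tasks x %d+%d steps", length(tasks),
      mcfg$inner_steps, mcfg$inner_steps)
  model <- meta_train(model, tasks, mcfg)
  lap(t0, "meta_train")

  t0 <- tic()
  hman <- cman[cman$device == cfg$evaluation$holdout, , drop = FALSE]
  if (nrow(hman) == 0) stop("no images for held-out device ",
                            cfg$evaluation$holdout)
  sp <- split_train_test(hman, ratio = cfg$evaluation$adapt_fraction,
                         seed = derive_seed(seed, "adapt"))
  say("[fine-tune] %d adaptation images, %d steps", nrow(sp$train),
      mcfg$finetune_steps)
  model <- fine_tune(model, manifest_dataset(sp$train, images), mcfg)
  model <- recalibrate_bn(model, manifest_dataset(sp$train, images),
                          seed = derive_seed(seed, "recalibrate"))
  lap(t0, "fine_tune")

  t0 <- tic()
  say("[evaluate] %d held-out images on device %s", nrow(sp$test),
      cfg$evaluation$holdout)
  report <- evaluate_model(model, manifest_dataset(sp$test, images),
                           threshold = cfg$evaluation$threshold)
  lap(t0, "evaluate")
  timings["total"] <- round(proc.time()[3] - t_all, 2)

  save_checkpoint(model, file.path(cfg$out_dir, "model.rds"))
  rj <- list(seed = seed, preset = cfg$preset,
             holdout = cfg$evaluation$holdout,
             n_adapt = nrow(sp$train), n_test = nrow(sp$test),
             metrics = report[c("precision", "recall", "f1", "auc_roc",
                                "accuracy")],
             confusion = report$confusion, timings = as.list(timings))
  jsonlite::write_json(rj, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(report = report, model = model, manifest = cman,
                 adapt_manifest = sp$train, test_manifest = sp$test,
                 timings = timings, config = cfg),
            class = "gingershift_run")
}

#' @export
print.gingershift_run <- function(x, ...) {
  cat(sprintf("end-to-end run (preset %s, seed %d)\n",
              x$config$preset, x$config$seed))
  cat(sprintf("held-out device %s: %d adapt / %d test images\n",
              x$config$evaluation$holdout, nrow(x$adapt_manifest),
              nrow(x$test_manifest)))
  print(x$report)
  cat("stage timings (s):",
      paste(names(x$timings), unname(x$timings), sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}
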