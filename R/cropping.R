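#' Region box
#'
#' A scored candidate region in the detection frame. Coordinates are
#' 0-based, half-open: the box covers pixels `[x0, x1) x [y0, y1)`.
#'
#' @param x0,y0,x1,y1 Corner coordinates in pixels, `x0 < x1`, `y0 < y1`.
#' @param score Confidence in `[0, 1]`.
#' @param category Integer label index (the fallback detector is
#'   class-agnostic and uses 1).
#' @return A `region_box` object.
#' @export
region_box <- function(x0, y0, x1, y1, score = 1, category = 1L) {
  if (!(x0 < x1 && y0 < y1)) stop("region_box requires x0 < x1 and y0 < y1")
  if (score < 0 || score > 1) stop("score must be in [0, 1]")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 score = score, category = as.integer(category)),
            class = "region_box")
}

box_area <- function(b) (b$x1 - b$x0) * (b$y1 - b$y0)

to_gray <- function(image) {
  if (length(dim(image)) == 3) {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else image
}

#' Deterministic background-segmentation detector
#'
#' Offline detector for photographs with a light, near-uniform background:
#' estimates the background level as a high quantile of the gray intensity,
#' thresholds a fixed margin below it, labels connected components, and
#' returns one box per sufficiently large component. Each box's score is the
#' component's fill fraction of its bounding box.
#'
#' @param image RGB array `(H, W, 3)` or gray matrix in `[0, 1]`.
#' @param background_quantile Quantile locating the background level.
#' @param min_area_fraction Minimum component area as a fraction of the
#'   image area.
#' @param margin Intensity margin below the background level used as the
#'   foreground threshold.
#' @return List of [region_box()] objects (possibly empty), in label order.
#' @export
fallback_detect <- function(image, background_quantile = 0.98,
                            min_area_fraction = 0.001, margin = 0.1) {
  gray <- to_gray(image)
  bg <- stats::quantile(gray, background_quantile, names = FALSE)
  mask <- gray < (bg - margin)
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(mask)
  H <- nrow(gray); W <- ncol(gray)
  min_area <- min_area_fraction * H * W
  boxes <- list()
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    y0 <- min(px[, 1]) - 1L; y1 <- max(px[, 1])
    x0 <- min(px[, 2]) - 1L; x1 <- max(px[, 2])
    boxes[[length(boxes) + 1L]] <-
      region_box(x0, y0, x1, y1,
                 score = nrow(px) / ((x1 - x0) * (y1 - y0)), category = 1L)
  }
  boxes
}

#' Dense anchor-grid proposal generator
#'
#' Emulates the proposal stage of a two-stage detector without any learned
#' weights: multi-scale, multi-aspect anchor boxes on a regular grid, each
#' scored by the fraction of foreground pixels it contains (foreground from
#' the same background threshold as [fallback_detect()]). Produces a
#' proposal pool of a thousand or more boxes on typical frames.
#'
#' @inheritParams fallback_detect
#' @param scales Box sizes as fractions of the frame's short side.
#' @param ratios Height/width aspect ratios.
#' @param stride_fraction Grid stride as a fraction of the short side.
#' @return List of [region_box()] objects.
#' @export
anchor_proposals <- function(image, scales = c(0.15, 0.25, 0.4, 0.6, 0.8),
                             ratios = c(0.5, 1, 2), stride_fraction = 1 / 40,
                             background_quantile = 0.98, margin = 0.1) {
  gray <- to_gray(image)
  H <- nrow(gray); W <- ncol(gray)
  bg <- stats::quantile(gray, background_quantile, names = FALSE)
  fg <- gray < (bg - margin)
  # integral image with a zero first row/column for O(1) box sums
  ii <- matrix(0, H + 1, W + 1)
  ii[-1, -1] <- apply(apply(fg, 2, cumsum), 1, cumsum) |> t()
  short <- min(H, W)
  stride <- max(4L, as.integer(round(short * stride_fraction)))
  boxes <- list()
  for (sc in scales) {
    for (ar in ratios) {
      bw <- as.integer(round(sc * short / sqrt(ar)))
      bh <- as.integer(round(sc * short * sqrt(ar)))
      if (bw < 4L || bh < 4L || bw > W || bh > H) next
      xs <- seq(0L, W - bw, by = stride)
      ys <- seq(0L, H - bh, by = stride)
      for (x0 in xs) for (y0 in ys) {
        s <- (ii[y0 + bh + 1, x0 + bw + 1] - ii[y0 + 1, x0 + bw + 1] -
                ii[y0 + bh + 1, x0 + 1] + ii[y0 + 1, x0 + 1]) / (bw * bh)
        boxes[[length(boxes) + 1L]] <-
          region_box(x0, y0, x0 + bw, y0 + bh, score = min(1, max(0, s)),
                     category = 1L)
      }
    }
  }
  boxes
}

detection_result <- function(boxes, frame_width, frame_height,
                             scale_x, scale_y) {
  stopifnot(scale_x > 0, scale_y > 0)
  structure(list(boxes = boxes, frame_width = frame_width,
                 frame_height = frame_height,
                 scale_x = scale_x, scale_y = scale_y),
            class = "detection_result")
}

#' Propose candidate specimen regions
#'
#' Resizes the image to a uniform detection frame (shorter side
#' `frame_short_side`), runs the detector, sorts the proposals by
#' descending score and truncates to `max_proposals` (default 1000,
#' matching the candidate-pool size used before region filtering). The
#' frame-to-original scale factors are recorded for mapping crops back.
#'
#' @param image RGB array `(H, W, 3)`.
#' @param detector `"fallback"` ([fallback_detect()]), `"anchor"`
#'   ([anchor_proposals()]), or any function mapping an image to a list of
#'   [region_box()] objects.
#' @param max_proposals Maximum number of proposals kept (`>= 1`).
#' @param frame_short_side Short side of the detection frame in pixels.
#' @param min_side Minimum acceptable input short side.
#' @param ... Passed to the detector.
#' @return A `detection_result`.
#' @export
propose_regions <- function(image, detector = c("fallback", "anchor"),
                            max_proposals = 1000, frame_short_side = 512,
                            min_side = 32, ...) {
  stopifnot(max_proposals >= 1)
  d <- dim(image)
  if (min(d[1], d[2]) < min_side)
    stop(sprintf("image shorter side (%d px) is below the detector minimum (%d px)",
                 min(d[1], d[2]), min_side))
  if (is.character(detector)) {
    detector <- switch(match.arg(detector),
                       fallback = fallback_detect, anchor = anchor_proposals)
  }
  if (d[1] <= d[2]) {
    fh <- as.integer(frame_short_side)
    fw <- as.integer(round(d[2] * frame_short_side / d[1]))
  } else {
    fw <- as.integer(frame_short_side)
    fh <- as.integer(round(d[1] * frame_short_side / d[2]))
  }
  frame <- if (fh == d[1] && fw == d[2]) image else
    cpp_resize_bilinear(image, fh, fw)
  boxes <- detector(frame, ...)
  if (length(boxes)) {
    ord <- order(-vapply(boxes, `[[`, 0, "score"))
    boxes <- boxes[ord]
    if (length(boxes) > max_proposals) boxes <- boxes[seq_len(max_proposals)]
  }
  detection_result(boxes, fw, fh, scale_x = d[2] / fw, scale_y = d[1] / fh)
}

#' Filter candidate regions
#'
#' Removes background-like and tiny-scale proposals: keeps boxes with
#' `score >= score_min` and area at least `area_min_fraction` of the frame
#' area, preserving the incoming score order.
#'
#' @param result A `detection_result` from [propose_regions()].
#' @param score_min Minimum score in `[0, 1]`.
#' @param area_min_fraction Minimum box area as a fraction of the frame.
#' @return List of surviving [region_box()] objects (possibly empty).
#' @export
filter_regions <- function(result, score_min = 0.5, area_min_fraction = 0.01) {
  stopifnot(inherits(result, "detection_result"),
            score_min >= 0, score_min <= 1,
            area_min_fraction >= 0, area_min_fraction <= 1)
  amin <- area_min_fraction * result$frame_width * result$frame_height
  Filter(function(b) b$score >= score_min && box_area(b) >= amin,
         result$boxes)
}

#' Select the primary (largest) region
#'
#' The specimen is taken to be the largest surviving region — this is also
#' what discards the ruler, whose footprint is smaller than the rhizome's.
#' Ties on area are broken by higher score, then by lower list index.
#'
#' @param boxes Non-empty list of [region_box()] objects.
#' @return The selected `region_box`.
#' @export
select_primary_region <- function(boxes) {
  if (length(boxes) == 0) stop("no specimen detected")
  areas <- vapply(boxes, box_area, 0)
  scores <- vapply(boxes, `[[`, 0, "score")
  best <- order(-areas, -scores, seq_along(boxes))[1]
  boxes[[best]]
}

#' Crop a region out of the original-resolution image
#'
#' Maps the box corners from the detection frame to the original image with
#' the recorded scale factors, rounds outward so the specimen is never
#' clipped, clips to the image bounds, and returns the sub-image.
#'
#' @param original RGB array at the original resolution.
#' @param box A [region_box()] in `result`'s detection frame.
#' @param result The `detection_result` the box came from.
#' @return RGB array containing the cropped region.
#' @export
crop_to_region <- function(original, box, result) {
  stopifnot(inherits(box, "region_box"), inherits(result, "detection_result"))
  d <- dim(original)
  x0 <- max(0L, as.integer(floor(box$x0 * result$scale_x)))
  x1 <- min(d[2], as.integer(ceiling(box$x1 * result$scale_x)))
  y0 <- max(0L, as.integer(floor(box$y0 * result$scale_y)))
  y1 <- min(d[1], as.integer(ceiling(box$y1 * result$scale_y)))
  if (x1 <= x0 || y1 <= y0) stop("degenerate crop: empty region after clipping")
  original[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
}

#' Crop a specimen image end to end
#'
#' Convenience chain: propose regions, filter, select the largest, crop.
#'
#' @inheritParams propose_regions
#' @inheritParams filter_regions
#' @return Cropped RGB array with attributes `"box"` and `"result"`.
#' @export
crop_image <- function(image, detector = "fallback", max_proposals = 1000,
                       frame_short_side = 512, score_min = 0.5,
                       area_min_fraction = 0.01, ...) {
  res <- propose_regions(image, detector = detector,
                         max_proposals = max_proposals,
                         frame_short_side = frame_short_side, ...)
  kept <- filter_regions(res, score_min, area_min_fraction)
  box <- select_primary_region(kept)
  out <- crop_to_region(image, box, res)
  attr(out, "box") <- box
  attr(out, "result") <- res
  out
}

#' Crop every image in a manifest
#'
#' Reads each image, crops the primary specimen region and writes the crop
#' (PNG) plus an updated manifest to `out_dir`.
#'
#' @param manifest Manifest `data.frame` from [generate_dataset()] or
#'   [read_manifest()].
#' @param in_dir Directory the manifest's paths are relative to.
#' @param out_dir Output directory for the cropped images.
#' @param ... Passed to [crop_image()].
#' @return The updated manifest `data.frame` (attribute `"manifest_path"`).
#' @export
crop_dataset <- function(manifest, in_dir, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- manifest
  for (i in seq_len(nrow(manifest))) {
    img <- load_image(file.path(in_dir, manifest$path[i]))
    crop <- crop_image(img, ...)
    fn <- paste0(manifest$sample_id[i], "_crop.png")
    png::writePNG(crop, file.path(out_dir, fn))
    out$path[i] <- fn
    out$height[i] <- dim(crop)[1]
    out$width[i] <- dim(crop)[2]
  }
  mp <- file.path(out_dir, "manifest.csv")
  utils::write.csv(out, mp, row.names = FALSE)
  attr(out, "manifest_path") <- mp
  out
}
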