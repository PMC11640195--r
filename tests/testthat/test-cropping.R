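test_that("region boxes validate their geometry", {
  expect_error(region_box(5, 0, 5, 10), "x0 < x1")
  expect_error(region_box(0, 0, 5, 10, score = 1.2), "score")
  b <- region_box(0, 0, 10, 10, 0.8)
  expect_equal(gingershift:::box_area(b), 100)
})

test_that("fallback detector finds the components it should", {
  # no foreground at all
  expect_length(fallback_detect(array(1, c(40, 40, 3))), 0)
  # blob plus smaller ruler: two boxes, specimen box has the larger area
  img <- blob_image(seed = 4, include_ruler = TRUE)
  boxes <- fallback_detect(img)
  expect_length(boxes, 2)
  areas <- vapply(boxes, gingershift:::box_area, 0)
  big <- boxes[[which.max(areas)]]
  expect_gt(max(areas), min(areas))
  # the largest box encloses the generator's blob mask (oracle: mask extents)
  mask <- attr(img, "mask")
  px <- which(mask, arr.ind = TRUE)
  expect_lte(big$x0, min(px[, 2]) - 1)
  expect_gte(big$x1, max(px[, 2]))
  expect_lte(big$y0, min(px[, 1]) - 1)
  expect_gte(big$y1, max(px[, 1]))
})

test_that("fallback boxes equal a brute-force pixel scan", {
  img <- blob_image(seed = 12, include_ruler = FALSE)
  boxes <- fallback_detect(img)
  expect_length(boxes, 1)
  # independent oracle: same threshold rule, exhaustive pixel scan
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  fg <- gray < (quantile(gray, 0.98, names = FALSE) - 0.1)
  px <- which(fg, arr.ind = TRUE)
  expect_equal(boxes[[1]]$x0, min(px[, 2]) - 1)
  expect_equal(boxes[[1]]$x1, max(px[, 2]))
  expect_equal(boxes[[1]]$y0, min(px[, 1]) - 1)
  expect_equal(boxes[[1]]$y1, max(px[, 1]))
  expect_equal(boxes[[1]]$score,
               nrow(px) / ((boxes[[1]]$x1 - boxes[[1]]$x0) *
                             (boxes[[1]]$y1 - boxes[[1]]$y0)))
})

test_that("propose_regions sorts, truncates and validates", {
  img <- blob_image(seed = 5, include_ruler = TRUE)
  res <- propose_regions(img, detector = "fallback", frame_short_side = 64)
  sc <- vapply(res$boxes, `[[`, 0, "score")
  expect_true(all(diff(sc) <= 0))
  expect_equal(res$scale_y * res$frame_height, dim(img)[1], tolerance = 0.02)
  # truncation keeps exactly the top-scoring box
  r1 <- propose_regions(img, detector = "fallback", max_proposals = 1,
                        frame_short_side = 64)
  expect_length(r1$boxes, 1)
  expect_equal(r1$boxes[[1]]$score, max(sc))
  # too-small input is rejected
  expect_error(propose_regions(array(1, c(16, 16, 3))), "minimum")
})

test_that("filter_regions matches a brute-force filter", {
  set.seed(21)
  boxes <- lapply(1:40, function(i) {
    x0 <- runif(1, 0, 80); y0 <- runif(1, 0, 60)
    region_box(x0, y0, x0 + runif(1, 1, 40), y0 + runif(1, 1, 30),
               score = runif(1))
  })
  res <- gingershift:::detection_result(boxes, 128, 96, 1, 1)
  # identity when thresholds are zero
  expect_identical(filter_regions(res, 0, 0), boxes)
  for (smin in c(0.25, 0.5)) {
    for (amin in c(0.005, 0.02)) {
      kept <- filter_regions(res, smin, amin)
      oracle <- list()
      for (b in boxes) {
        if (b$score >= smin &&
            (b$x1 - b$x0) * (b$y1 - b$y0) >= amin * 128 * 96)
          oracle[[length(oracle) + 1L]] <- b
      }
      expect_identical(kept, oracle)
    }
  }
})

test_that("largest-region selection follows the tie rules", {
  b100 <- region_box(0, 0, 10, 10, 0.1)
  b25 <- region_box(0, 0, 5, 5, 0.99)
  expect_identical(select_primary_region(list(b25, b100)), b100)
  # equal areas: higher score wins
  t1 <- region_box(0, 0, 10, 10, 0.5)
  t2 <- region_box(5, 5, 15, 15, 0.9)
  expect_identical(select_primary_region(list(t1, t2)), t2)
  # equal area and score: first in list wins
  expect_identical(select_primary_region(list(t1, region_box(1, 1, 11, 11, 0.5))),
                   t1)
  expect_error(select_primary_region(list()), "no specimen")
  # random boxes: argmax area agrees with exhaustive comparison
  set.seed(33)
  for (rep in 1:5) {
    boxes <- lapply(1:10, function(i) {
      x0 <- runif(1, 0, 50); y0 <- runif(1, 0, 50)
      region_box(x0, y0, x0 + runif(1, 1, 30), y0 + runif(1, 1, 30),
                 runif(1))
    })
    areas <- vapply(boxes, gingershift:::box_area, 0)
    expect_identical(select_primary_region(boxes), boxes[[which.max(areas)]])
  }
})

test_that("crop mapping scales, rounds outward and clips", {
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  res <- gingershift:::detection_result(list(), 40, 40, 1, 1)
  crop <- crop_to_region(img, region_box(0, 0, 10, 10), res)
  expect_identical(crop, img[1:10, 1:10, , drop = FALSE])
  # frame 512 wide mapped back to a 4032-wide original: scale 7.875
  res2 <- gingershift:::detection_result(list(), 512, 384, 4032 / 512,
                                         3024 / 384)
  expect_equal(res2$scale_x, 7.875)
  big <- array(0, c(3024, 4032, 3))
  crop2 <- crop_to_region(big, region_box(16, 8, 32, 24), res2)
  # floor(16 * 7.875) = 126, ceiling(32 * 7.875) = 252
  expect_equal(dim(crop2)[2], 252 - 126)
  # a box mapping entirely past the image bounds clips to nothing
  expect_error(crop_to_region(img, region_box(5, 5, 10, 10),
                              gingershift:::detection_result(list(), 40, 40,
                                                             10, 10)),
               "degenerate")
})

test_that("the cropped region keeps the specimen and drops the ruler", {
  for (seed in c(2, 9, 17, 31)) {
    img <- blob_image(seed = seed, include_ruler = TRUE)
    mask <- attr(img, "mask")
    crop <- crop_image(img, frame_short_side = 64)
    box <- attr(crop, "box"); res <- attr(crop, "result")
    # map the chosen box back to original coordinates
    x0 <- floor(box$x0 * res$scale_x); x1 <- ceiling(box$x1 * res$scale_x)
    y0 <- floor(box$y0 * res$scale_y); y1 <- ceiling(box$y1 * res$scale_y)
    inside <- mask[(y0 + 1):min(nrow(mask), y1),
                   (x0 + 1):min(ncol(mask), x1)]
    expect_gte(sum(inside) / sum(mask), 0.99)  # >= 99% of blob pixels kept
    rmask <- attr(img, "ruler_mask")
    rin <- rmask[(y0 + 1):min(nrow(mask), y1), (x0 + 1):min(ncol(mask), x1)]
    expect_lt(sum(rin) / sum(rmask), 0.5)  # the ruler was not selected
  }
})

test_that("cropping an already-cropped specimen is near-idempotent", {
  img <- blob_image(seed = 8, include_ruler = FALSE)
  c1 <- crop_image(img, frame_short_side = 64)
  c2 <- crop_image(c1, frame_short_side = 64, min_side = 16)
  # IoU of the second crop (in c1's frame) with all of c1
  a1 <- prod(dim(c1)[1:2])
  a2 <- prod(dim(c2)[1:2])
  expect_gte(a2 / a1, 0.95)
})

test_that("crop_dataset writes crops and an updated manifest", {
  out <- withr::local_tempdir()
  man <- generate_dataset(list(small_profile("A", 96, 72)), c(HS = 2, NS = 1),
                          file.path(out, "img"), seed = 3,
                          scene = small_scene())
  cman <- crop_dataset(man, file.path(out, "img"), file.path(out, "crops"),
                       frame_short_side = 48, min_side = 24)
  expect_equal(nrow(cman), 3)
  expect_true(all(cman$width <= man$width & cman$height <= man$height))
  imgs <- load_images(cman, dir = file.path(out, "crops"))
  expect_true(all(mapply(function(i, w, h) all(dim(i) == c(h, w, 3)),
                         imgs, cman$width, cman$height)))
})
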