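test_that("sliding windows enumerate and clamp origins per axis", {
  spec <- tileSpec()  # 9504 x 6336 window, step 5000
  # window equals the image: single origin
  w1 <- slidingWindows(9504, 6336, spec)
  expect_equal(unname(w1[, ]), c(0, 0))
  # 5000 + 9504 = 14504 exactly: no clamp needed
  w2 <- slidingWindows(14504, 6336, spec)
  expect_equal(unname(w2[, "x"]), c(0, 5000))
  # 16000: final origin clamped to 16000 - 9504
  w3 <- slidingWindows(16000, 6336, spec)
  expect_equal(unname(w3[, "x"]), c(0, 5000, 6496))
  # window larger than source: flagged single cropped window
  w4 <- slidingWindows(5000, 5000, spec)
  expect_equal(nrow(w4), 1)
  expect_true(attr(w4, "cropped"))
})

test_that("clamped windows cover every source pixel", {
  set.seed(91)
  for (i in 1:30) {
    sw <- sample(9504:40000, 1)
    sh <- sample(6336:30000, 1)
    org <- slidingWindows(sw, sh, tileSpec())
    xs <- sort(unique(org[, "x"])); ys <- sort(unique(org[, "y"]))
    cover <- function(orig, win, src) {
      end <- 0
      for (o in orig) {
        if (o > end) return(FALSE)
        end <- max(end, o + win)
      }
      end >= src
    }
    expect_true(cover(xs, 9504, sw))
    expect_true(cover(ys, 6336, sh))
  }
})

test_that("box cropping clips, translates and applies the 1/3 area rule", {
  win <- c(100, 100, 50, 50)
  inside <- leafBoxes(110, 110, 130, 130)
  out <- cropBoxes(inside, win)
  expect_equal(unname(out[1, ]), c(10, 10, 30, 30))
  # fully outside: dropped
  expect_equal(nrow(cropBoxes(leafBoxes(0, 0, 50, 50), win)), 0)
  # 40% inside kept, 20% inside dropped (area-ratio arithmetic)
  b40 <- leafBoxes(96, 110, 106, 120)   # 4 of 10 width inside
  expect_equal(nrow(cropBoxes(b40, win)), 1)
  b20 <- leafBoxes(92, 110, 102, 120)   # 2 of 10 width inside
  expect_equal(nrow(cropBoxes(b20, win)), 0)
})

test_that("count screening uses the >= 50 boundary (and 200 for full images)", {
  expect_false(screenTile(49))
  expect_true(screenTile(50))
  expect_false(screenTile(0))
  expect_false(screenTile(199, minBoxes = 200))
  expect_true(screenTile(200, minBoxes = 200))
})

test_that("density statistics truncate to two decimals", {
  expect_equal(densityStats(1696, 85375)$density, 50.33)
  expect_equal(densityStats(361, 13564)$density, 37.57)
  expect_equal(densityStats(6422, 271553)$density, 42.28)
  expect_equal(densityStats(10, 0)$density, 0)
  expect_error(densityStats(0, 10), "positive")
  # truncation invariant: density * images <= boxes < (density + 0.01) * images
  set.seed(92)
  for (i in 1:20) {
    im <- sample(50:5000, 1); bx <- sample(0:200000, 1)
    d <- densityStats(im, bx)$density
    expect_lte(d * im, bx + 1e-6)
    expect_gt((d + 0.01) * im, bx - 1e-6)
  }
})

test_that("tiling a dataset screens sparse tiles and is idempotent on tiles", {
  # synthetic source: one big image with clustered boxes
  set.seed(93)
  n <- 300
  ann <- data.frame(id = seq_len(n), image_id = 1L, category_id = 1L,
                    x = runif(n, 0, 11000), y = runif(n, 0, 6000),
                    width = runif(n, 40, 120), height = runif(n, 40, 120))
  ann$area <- ann$width * ann$height
  coco <- list(images = data.frame(id = 1L, file_name = "src.png",
                                   width = 12000, height = 6400),
               annotations = ann,
               categories = data.frame(id = 1L, name = "leaf"))
  tiled <- tileDataset(coco, tileSpec(), minBoxes = 50)
  expect_true(all(tiled$tiles$boxes >= 50))
  expect_equal(nrow(tiled$annotations),
               sum(tiled$tiles$boxes))
  # re-tiling an emitted tile with the same spec returns the tile itself
  if (nrow(tiled$images) > 0) {
    sub <- list(images = tiled$images[1, , drop = FALSE],
                annotations = tiled$annotations[
                  tiled$annotations$image_id == tiled$images$id[1], , drop = FALSE],
                categories = coco$categories)
    again <- tileDataset(sub, tileSpec(), minBoxes = 50)
    expect_equal(nrow(again$images), 1)
    expect_equal(nrow(again$annotations), nrow(sub$annotations))
    expect_equal(again$annotations[, c("x", "y", "width", "height")],
                 sub$annotations[, c("x", "y", "width", "height")],
                 ignore_attr = TRUE)
  }
})
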