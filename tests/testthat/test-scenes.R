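test_that("scene generation is seeded, deterministic and self-consistent", {
  spec <- sceneSpec(width = 96, height = 96, lambda = 15, seed = 71)
  sc1 <- sampleScene(spec)
  sc2 <- sampleScene(spec)
  expect_identical(sceneImage(sc1), sceneImage(sc2))
  expect_identical(sceneInstances(sc1), sceneInstances(sc2))
  expect_identical(sceneOwner(sc1), sceneOwner(sc2))

  inst <- sceneInstances(sc1)
  expect_true(all(inst$visibleFraction >= 0 & inst$visibleFraction <= 1))
  # pixel partition: visible areas + background = image area
  expect_equal(sum(inst$visibleArea) + sum(sceneOwner(sc1) == 0), 96 * 96)
  # image values are valid RGB
  expect_true(all(sceneImage(sc1) >= 0 & sceneImage(sc1) <= 1))
})

test_that("an empty canopy renders pure background", {
  sc <- sampleScene(sceneSpec(width = 32, height = 32, lambda = 0, seed = 72))
  expect_equal(nrow(sceneInstances(sc)), 0)
  expect_true(all(sceneOwner(sc) == 0))
  expect_equal(nrow(annotateScene(sc)), 0)
})

test_that("later leaves occlude earlier ones down to zero visibility", {
  # craft an occlusion by sampling until a leaf is fully painted over
  found <- FALSE
  for (s in 1:40) {
    sc <- sampleScene(sceneSpec(width = 64, height = 64, lambda = 30,
                                axisA = c(14, 20), axisB = c(9, 14), seed = s))
    inst <- sceneInstances(sc)
    hidden <- inst$visibleFraction == 0 & inst$fullArea > 0
    if (any(hidden)) { found <- TRUE; break }
  }
  expect_true(found)
  # no pixel of a fully hidden leaf remains in the owner matrix
  hid <- inst$id[which(hidden)[1]]
  expect_false(any(sceneOwner(sc) == hid))
})

test_that("annotation boxes bound the visible pixels only and respect the 1/3 rule", {
  sc <- small_scene(73, lambda = 20)
  inst <- sceneInstances(sc)
  boxes <- annotateScene(sc)
  ids <- attr(boxes, "leafIds")
  thr <- 1 / 3
  expect_setequal(ids, inst$id[inst$visibleFraction >= thr & inst$visibleArea > 0])
  # pixel-scan oracle for each annotated leaf
  own <- sceneOwner(sc)
  for (j in seq_along(ids)) {
    px <- which(own == ids[j], arr.ind = TRUE)
    expect_equal(unname(boxes[j, ]),
                 c(min(px[, 2]) - 1, min(px[, 1]) - 1, max(px[, 2]), max(px[, 1])))
  }
  # an unoccluded leaf's box equals its full-ellipse bounding box: the last
  # painted leaf is never occluded
  last <- inst[nrow(inst), ]
  if (last$visibleFraction == 1 && last$id %in% ids) {
    jb <- boxes[which(ids == last$id), ]
    full_px <- which(own == last$id, arr.ind = TRUE)
    expect_equal(nrow(full_px), last$fullArea)
  }
  # raising the threshold only removes annotations
  strict <- annotateScene(sc, minVisibleFraction = 0.9)
  expect_lte(nrow(strict), nrow(boxes))
  expect_true(all(attr(strict, "leafIds") %in% ids |
                    inst$visibleFraction[match(attr(strict, "leafIds"), inst$id)] >= 0.9))
})

test_that("realized density is monotone in lambda", {
  mean_boxes <- function(lam) {
    mean(vapply(1:15, function(i) {
      nrow(annotateScene(sampleScene(sceneSpec(lambda = lam, seed = 1000 * lam + i))))
    }, numeric(1)))
  }
  d10 <- mean_boxes(10); d30 <- mean_boxes(30); d50 <- mean_boxes(50)
  expect_lt(d10, d30)
  expect_lt(d30, d50)
})

test_that("COCO round trip preserves boxes exactly and recounts annotations", {
  scenes <- lapply(1:3, function(i) small_scene(80 + i, lambda = 8))
  dir <- file.path(tempdir(), "coco_rt")
  path <- writeCocoDataset(scenes, dir, writeImages = TRUE)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(dir, "scene_0001.png")))
  coco <- readCocoDataset(path)
  expect_equal(nrow(coco$images), 3)
  expect_equal(coco$categories$name, "leaf")
  # recount oracle: annotation count equals the sum of surviving instances
  want <- sum(vapply(scenes, function(s) nrow(annotateScene(s)), numeric(1)))
  expect_equal(nrow(coco$annotations), want)
  # boxes survive the round trip bit-exactly
  gts <- cocoGroundTruths(coco)
  for (i in 1:3) {
    expect_equal(unname(gts[[as.character(i)]]$boxes[, 1:4]),
                 unname(annotateScene(scenes[[i]])[, 1:4]))
  }
  # empty dataset still produces valid JSON
  p0 <- writeCocoDataset(list(), file.path(tempdir(), "coco_empty"))
  c0 <- readCocoDataset(p0)
  expect_equal(nrow(c0$annotations), 0)
})
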