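test_that("greedy matching follows the COCO convention", {
  gt <- leafBoxes(c(0, 10), c(0, 10), c(4, 14), c(4, 14))
  # detections identical to gts: all TP, no misses
  m <- greedyMatch(gt, c(0.9, 0.8), gt)
  expect_true(all(m$tp))
  expect_equal(m$fn, 0)
  # no detections
  m0 <- greedyMatch(leafBoxes(numeric(0), numeric(0), numeric(0), numeric(0)),
                    numeric(0), gt)
  expect_equal(m0$fn, 2)
  # ranked hit, miss, hit
  dets <- rbind(gt[1, ], leafBoxes(100, 100, 104, 104), gt[2, ])
  m3 <- greedyMatch(dets, c(0.9, 0.8, 0.7), gt)
  expect_equal(m3$tp, c(TRUE, FALSE, TRUE))
  # each gt matched at most once: a duplicate detection becomes FP
  dup <- rbind(gt[1, ], gt[1, ])
  m4 <- greedyMatch(dup, c(0.9, 0.8), gt[1, , drop = FALSE])
  expect_equal(m4$tp, c(TRUE, FALSE))
  # maxDets caps the ranked list
  m5 <- greedyMatch(dup, c(0.9, 0.8), gt[1, , drop = FALSE], maxDets = 1)
  expect_length(m5$tp, 1)
})

test_that("101-point AP reproduces hand-enumerated envelopes", {
  expect_equal(apFromRankedFlags(c(TRUE, TRUE), 2), 1)
  expect_equal(apFromRankedFlags(c(FALSE, FALSE, FALSE), 3), 0)
  expect_equal(apFromRankedFlags(logical(0), 2), 0)
  expect_equal(apFromRankedFlags(c(TRUE), 0), 0)
  # worked example: (TP, FP, TP) over 2 gts
  expect_equal(apFromRankedFlags(c(TRUE, FALSE, TRUE), 2),
               (51 * 1 + 50 * (2 / 3)) / 101, tolerance = 1e-12)
  # literal area-under-curve mode integrates the raw step curve
  expect_equal(apFromRankedFlags(c(TRUE, FALSE, TRUE), 2, mode = "auc"),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
})

test_that("AP never improves when a TP flips to FP", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    flags <- stats::runif(n) > 0.5
    g <- max(sum(flags), 1)
    ap <- apFromRankedFlags(flags, g)
    pos <- which(flags)
    if (length(pos) == 0) next
    flags2 <- flags
    flags2[sample(pos, 1)] <- FALSE
    expect_lte(apFromRankedFlags(flags2, g), ap + 1e-12)
  }
})

test_that("evaluation summary agrees with the independent reference evaluator", {
  scenes <- lapply(1:5, function(i) small_scene(400 + i, lambda = 8))
  dets <- list(); gts <- list()
  for (i in seq_along(scenes)) {
    id <- as.character(i)
    gt <- annotateScene(scenes[[i]])
    gts[[id]] <- list(boxes = gt)
    dets[[id]] <- pseudo_detections(gt, seed = 500 + i, width = 64, height = 64)
  }
  got <- metricValues(evaluateDetections(dets, gts))
  want <- oracle_evaluate(dets, gts)
  expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-6)
  expect_gte(got["AR300"], got["AR100"])

  # a perfect detector scores 1 everywhere
  perfect <- lapply(gts, function(g) list(boxes = g$boxes,
                                          scores = rep(1, nrow(g$boxes))))
  pv <- metricValues(evaluateDetections(perfect, gts))
  expect_equal(unname(pv[c("mAP", "mAP50", "AR300", "precision", "recall", "F1")]),
               rep(1, 6))

  # empty detections: all zeros
  none <- lapply(gts, function(g)
    list(boxes = leafBoxes(numeric(0), numeric(0), numeric(0), numeric(0)),
         scores = numeric(0)))
  expect_equal(max(metricValues(evaluateDetections(none, gts))), 0)

  expect_error(evaluateDetections(list(zzz = dets[[1]]), gts), "unknown image")
})

test_that("summary export writes JSON and a table row", {
  gts <- list(`1` = list(boxes = leafBoxes(0, 0, 4, 4)))
  dets <- list(`1` = list(boxes = leafBoxes(0, 0, 4, 4), scores = 0.9))
  s <- evaluateDetections(dets, gts)
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".txt")
  writeSummary(s, jf, tf)
  j <- jsonlite::read_json(jf)
  expect_equal(j$mAP, 1)
  expect_match(readLines(tf)[1], "mAP@50")
})
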