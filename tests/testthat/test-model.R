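test_that("forward pass honours the query-count contracts", {
  m <- small_model(seed = 2)
  set.seed(101)
  img <- sceneImage(small_scene(102, lambda = 5))
  # threshold 0 -> exactly nOri boxes; threshold 1 -> none
  all_out <- inferBoxes(m, img, scoreThreshold = 0)
  expect_equal(nrow(all_out$boxes), 30)
  expect_equal(length(all_out$scores), 30)
  none <- inferBoxes(m, img, scoreThreshold = 1.0000001)
  expect_equal(nrow(none$boxes), 0)
  # both branches are visible in the training-time view
  q <- modelQueries(m, img)
  expect_equal(nrow(q$ori$boxes), 30)
  expect_equal(nrow(q$extra$boxes), 30)
  expect_true(all(q$ori$boxes >= 0 & q$ori$boxes <= 1))
})

test_that("the extra branch is provably inactive at evaluation time", {
  img <- sceneImage(small_scene(103, lambda = 5))
  m_on <- small_model(seed = 4, cqr = TRUE)
  m_off <- small_model(seed = 4, cqr = FALSE)
  a <- inferBoxes(m_on, img, scoreThreshold = 0)
  b <- inferBoxes(m_off, img, scoreThreshold = 0)
  # same weights, CQR toggled: evaluation outputs identical, count = nOri
  expect_equal(a$boxes, b$boxes)
  expect_equal(a$scores, b$scores)
  expect_equal(nrow(a$boxes), 30)
  # and the eval path never exposes extra queries
  expect_null(modelQueries(m_off, img)$extra)
})

test_that("NMS culling shrinks the matcher input, strictly so for duplicates", {
  cfg <- matchConfig()
  gt <- cbind(0.5, 0.5, 0.3, 0.3)
  dup <- rbind(gt, gt, gt, cbind(0.2, 0.2, 0.1, 0.1))
  comp <- cqrCompose(dup, c(0.9, 0.8, 0.7, 0.6), NULL, NULL, gt, cfg)
  expect_lt(length(comp$keptOri), nrow(dup))
  expect_lte(length(comp$keptOri), nrow(dup))
})

test_that("CQR multiplies supervision on crowded scenes versus one-to-one", {
  sc <- sampleScene(sceneSpec(width = 128, height = 128, lambda = 30,
                              axisA = c(12, 20), axisB = c(8, 13), seed = 104))
  gt <- annotateScene(sc)
  gtc <- cornerToCenter(gt, 128, 128)
  m <- buildModel(modelConfig(channels = 16, nOri = 60, nExtra = 60), seed = 5)
  q <- modelQueries(m, sceneImage(sc))
  cfg <- matchConfig(k = 4)
  comp <- cqrCompose(q$ori$boxes, q$ori$scores, q$extra$boxes, q$extra$scores,
                     gtc, cfg)
  with_cqr <- supervisedPerGt(list(comp$ori, comp$extra), nrow(gt))
  one2one <- supervisedPerGt(
    list(hungarianMatch(buildCostMatrix(q$ori$boxes, q$ori$scores, gtc, cfg))),
    nrow(gt))
  expect_gt(sum(with_cqr >= 2), sum(one2one >= 2))
  expect_true(all(one2one <= 1))
})

test_that("training is deterministic per seed and losses stay finite", {
  scenes <- smoke_scenes(6)
  m1 <- small_model(seed = 6)
  r1 <- trainModel(m1, scenes, trainConfig(batchSize = 1, iterations = 8, seed = 9))
  m2 <- small_model(seed = 6)
  r2 <- trainModel(m2, scenes, trainConfig(batchSize = 1, iterations = 8, seed = 9))
  expect_identical(r1$loss, r2$loss)
  expect_true(all(is.finite(r1$loss)))
  m3 <- small_model(seed = 6)
  r3 <- trainModel(m3, scenes, trainConfig(batchSize = 1, iterations = 8, seed = 10))
  expect_false(identical(r1$loss, r3$loss))
})

test_that("every ablation toggle changes behaviour", {
  scenes <- smoke_scenes(4)
  img <- sceneImage(scenes[[1]])
  base_loss <- function(...) {
    m <- small_model(seed = 7, ...)
    trainModel(m, scenes, trainConfig(batchSize = 1, iterations = 4, seed = 11))$loss
  }
  full <- base_loss()
  expect_false(identical(full, base_loss(cqr = FALSE)))
  expect_false(identical(full, base_loss(auxHead = FALSE)))
  expect_false(identical(full, base_loss(pfpn = FALSE)))
  # P-FPN toggle changes inference too (it sits on the eval path)
  expect_gt(max(abs(inferBoxes(small_model(seed = 7), img, 0)$scores -
                      inferBoxes(small_model(seed = 7, pfpn = FALSE), img, 0)$scores)),
            0)
  # all-off baseline still trains
  off <- base_loss(cqr = FALSE, auxHead = FALSE, pfpn = FALSE)
  expect_true(all(is.finite(off)))
})
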