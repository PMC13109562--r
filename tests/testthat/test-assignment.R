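test_that("cost matrix matches a hand-computed oracle and its degenerate cases", {
  cfg <- matchConfig()
  # prediction identical to gt with probability 1 -> zero cost
  pb <- cbind(0.5, 0.5, 0.2, 0.2)
  expect_equal(as.numeric(buildCostMatrix(pb, 1, pb, cfg)), 0)
  # no ground truths: valid 0-column matrix
  m0 <- buildCostMatrix(pb, 0.5, NULL, cfg)
  expect_equal(dim(m0), c(1L, 0L))
  expect_error(buildCostMatrix(pb, c(0.5, 0.2), pb), "mismatch")

  set.seed(21)
  P <- 4; G <- 3
  pred <- cbind(runif(P, .3, .7), runif(P, .3, .7), runif(P, .1, .3), runif(P, .1, .3))
  probs <- runif(P)
  gt <- cbind(runif(G, .3, .7), runif(G, .3, .7), runif(G, .1, .3), runif(G, .1, .3))
  got <- buildCostMatrix(pred, probs, gt, cfg)
  for (i in seq_len(P)) {
    for (j in seq_len(G)) {
      l1 <- mean(abs(pred[i, ] - gt[j, ]))
      pc <- c(pred[i, 1] - pred[i, 3] / 2, pred[i, 2] - pred[i, 4] / 2,
              pred[i, 1] + pred[i, 3] / 2, pred[i, 2] + pred[i, 4] / 2)
      gc_ <- c(gt[j, 1] - gt[j, 3] / 2, gt[j, 2] - gt[j, 4] / 2,
               gt[j, 1] + gt[j, 3] / 2, gt[j, 2] + gt[j, 4] / 2)
      iw <- max(0, min(pc[3], gc_[3]) - max(pc[1], gc_[1]))
      ih <- max(0, min(pc[4], gc_[4]) - max(pc[2], gc_[2]))
      inter <- iw * ih
      uni <- (pc[3] - pc[1]) * (pc[4] - pc[2]) +
        (gc_[3] - gc_[1]) * (gc_[4] - gc_[2]) - inter
      enc <- (max(pc[3], gc_[3]) - min(pc[1], gc_[1])) *
        (max(pc[4], gc_[4]) - min(pc[2], gc_[2]))
      giou <- inter / uni - (enc - uni) / enc
      expect_equal(got[i, j],
                   cfg$wCls * (1 - probs[i]) + cfg$wL1 * l1 + cfg$wGIoU * (1 - giou),
                   tolerance = 1e-12)
    }
  }
})

test_that("raising the foreground probability never increases the cost", {
  set.seed(22)
  pred <- cbind(runif(5, .3, .7), runif(5, .3, .7), runif(5, .1, .3), runif(5, .1, .3))
  gt <- pred[1:2, , drop = FALSE]
  lo <- buildCostMatrix(pred, rep(0.2, 5), gt)
  hi <- buildCostMatrix(pred, rep(0.9, 5), gt)
  expect_true(all(hi <= lo))
})

test_that("Hungarian matching solves small instances exactly", {
  a <- hungarianMatch(matrix(3.5, 1, 1))
  expect_equal(unname(assignmentPairs(a)), matrix(c(1L, 1L), 1, 2))
  expect_equal(totalCost(a), 3.5)
  a2 <- hungarianMatch(matrix(c(1, 2, 2, 1), 2, 2))
  expect_equal(totalCost(a2), 2)
  # 2 predictions, 1 gt: the cheaper prediction wins
  a3 <- hungarianMatch(matrix(c(0.5, 0.2), 2, 1))
  expect_equal(unname(assignmentPairs(a3)), matrix(c(2L, 1L), 1, 2))
  expect_equal(totalCost(a3), 0.2)
})

test_that("Hungarian total cost equals the brute-force permutation minimum", {
  set.seed(23)
  for (trial in 1:200) {
    P <- sample(1:6, 1); G <- sample(1:6, 1)
    cost <- matrix(round(stats::runif(P * G), 4), P, G)
    a <- hungarianMatch(cost)
    expect_equal(nrow(assignmentPairs(a)), min(P, G))
    expect_equal(totalCost(a), oracle_assignment_min(cost), tolerance = 1e-10)
  }
})

test_that("Top-K matching equals explicit sequential rounds and obeys the count law", {
  # k = 1 reduces to plain Hungarian
  set.seed(24)
  cost <- matrix(runif(12), 4, 3)
  expect_equal(assignmentPairs(topkHungarianMatch(cost, 1)),
               assignmentPairs(hungarianMatch(cost)))
  # worked example: G = 1, P = 3, costs (0.3, 0.1, 0.2), k = 2
  tk <- topkHungarianMatch(matrix(c(0.3, 0.1, 0.2), 3, 1), 2)
  p <- assignmentPairs(tk)
  expect_equal(sort(p[, "pred"]), c(2L, 3L))
  expect_equal(unique(p[, "gt"]), 1L)
  # pool exhaustion: all three predictions assigned
  expect_equal(nrow(assignmentPairs(topkHungarianMatch(matrix(c(0.3, 0.1, 0.2), 3, 1), 4))), 3)

  for (trial in 1:150) {
    P <- sample(1:12, 1); G <- sample(1:4, 1); k <- sample(1:4, 1)
    cost <- matrix(stats::runif(P * G), P, G)
    got <- assignmentPairs(topkHungarianMatch(cost, k))
    want <- oracle_topk_rounds(cost, k)
    expect_equal(nrow(got), min(k * G, P))
    expect_equal(got[order(got[, 1]), , drop = FALSE],
                 want[order(want[, 1]), , drop = FALSE])
    expect_true(all(tabulate(got[, "gt"], G) <= k))
    expect_false(anyDuplicated(got[, "pred"]) > 0)
  }
})

test_that("a larger prediction pool never increases the assignment cost", {
  set.seed(25)
  for (trial in 1:50) {
    G <- sample(1:3, 1)
    big <- matrix(stats::runif(10 * G), 10, G)
    small_cost <- totalCost(hungarianMatch(big[1:5, , drop = FALSE]))
    big_cost <- totalCost(hungarianMatch(big))
    expect_lte(big_cost, small_cost + 1e-12)
  }
})

test_that("CQR composition culls duplicate originals and matches extras one-to-many", {
  cfg <- matchConfig(k = 4, nmsThreshold = 0.7)
  gt <- cbind(c(0.3, 0.7), c(0.3, 0.7), c(0.2, 0.2), c(0.2, 0.2))
  # no extras, no overlapping originals -> plain Hungarian over all originals
  ori <- cbind(c(0.3, 0.7), c(0.3, 0.7), c(0.19, 0.21), c(0.2, 0.2))
  comp <- cqrCompose(ori, c(0.8, 0.9), NULL, NULL, gt, cfg)
  expect_equal(length(comp$keptOri), 2)
  expect_equal(nrow(assignmentPairs(comp$ori)), 2)
  expect_equal(nrow(assignmentPairs(comp$extra)), 0)

  # two duplicate originals over one gt: the lower-scored one is culled
  gt1 <- cbind(0.5, 0.5, 0.2, 0.2)
  dup <- rbind(gt1, gt1)
  comp2 <- cqrCompose(dup, c(0.6, 0.9), NULL, NULL, gt1, cfg)
  expect_equal(comp2$keptOri, 2L)
  expect_equal(unname(assignmentPairs(comp2$ori)[, "pred"]), 2L)

  # G = 2, 8 extras, k = 4 -> count law min(k*G, P) = 8
  set.seed(26)
  extras <- cbind(runif(8, .2, .8), runif(8, .2, .8), runif(8, .1, .3), runif(8, .1, .3))
  comp3 <- cqrCompose(ori, c(0.8, 0.9), extras, runif(8), gt, cfg)
  expect_equal(nrow(assignmentPairs(comp3$extra)), 8)
  expect_true(all(tabulate(assignmentPairs(comp3$extra)[, "gt"], 2) <= 4))
})

test_that("combined loss weights the extra branch down", {
  expect_equal(combinedLoss(2, 1, 0.5), 2.5)
  expect_equal(combinedLoss(2, 1, 0), 2)
  expect_equal(combinedLoss(2, 0, 0.7), 2)
  expect_error(combinedLoss(2, 1, -0.1), "nonnegative")
})
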