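test_that("FeaturePyramid enforces its shape invariants", {
  p <- featurePyramid(list(array(0, c(8, 16, 16)), array(0, c(8, 8, 8))))
  expect_equal(nLevels(p), 2)
  expect_error(featurePyramid(list(array(0, c(8, 16, 16)), array(0, c(4, 8, 8)))),
               "channel")
  expect_error(featurePyramid(list(array(0, c(8, 16, 16)), array(0, c(8, 9, 8)))),
               "halve")
})

test_that("top transform preserves shape and matches the straight-line oracle", {
  params <- pfpnParams(8, 2, seed = 31)
  set.seed(32)
  x <- array(rnorm(8 * 16 * 16), c(8, 16, 16))
  out <- topTransform(x, params)
  expect_equal(dim(out), c(8, 16, 16))
  expect_equal(out, oracle_top_transform(x, params$top), tolerance = 1e-10)
  # zero input with zero biases stays zero (the chain is linear)
  expect_equal(max(abs(topTransform(array(0, c(8, 4, 4)), params))), 0)
  expect_error(topTransform(array(0, c(4, 4, 4)), params), "channel")
})

test_that("AFA gates stay in (0,1) and match the straight-line oracles", {
  params <- pfpnParams(8, 2, seed = 33)
  set.seed(34)
  p1 <- array(rnorm(8 * 12 * 12), c(8, 12, 12))
  p2 <- array(rnorm(8 * 12 * 12), c(8, 12, 12))

  fs <- afaSpatialGate(p1, p2, params)
  expect_equal(dim(fs), c(1, 12, 12))
  expect_true(all(fs > 0 & fs < 1))
  expect_equal(fs, oracle_spatial_gate(p1, p2, params$afa[[1]]), tolerance = 1e-10)

  fc <- afaChannelGate(p1, p2, params)
  expect_equal(dim(fc), c(8, 12, 12))
  pc <- attr(fc, "channelWeights")
  expect_length(pc, 16)  # 2C channel weights
  expect_true(all(pc > 0 & pc < 1))
  ofc <- oracle_channel_gate(p1, p2, params$afa[[1]])
  expect_equal(unname(pc), unname(ofc$pc), tolerance = 1e-10)
  expect_equal(as.numeric(fc), as.numeric(ofc$fc), tolerance = 1e-10)

  fused <- afaFuse(p1, p2, params)
  expect_equal(fused, oracle_afa_fuse(p1, p2, params$afa[[1]]), tolerance = 1e-10)
  # the spatial gate is < 1 everywhere, so it can only attenuate
  expect_true(all(abs(fused) <= abs(fc) + 1e-12))
  expect_error(afaFuse(p1, array(0, c(8, 6, 6)), params), "same shape")

  # zero inputs with zero biases: Sigmoid(0) = 0.5 exactly
  z <- array(0, c(8, 12, 12))
  params0 <- params
  params0$afa[[1]]$sp1_b <- 0
  expect_equal(unique(as.numeric(afaSpatialGate(z, z, params0))), 0.5)
})

test_that("progressive fusion preserves shapes and equals the unrolled oracle", {
  params <- pfpnParams(8, 3, seed = 35)
  set.seed(36)
  lv <- list(array(rnorm(8 * 16 * 16), c(8, 16, 16)),
             array(rnorm(8 * 8 * 8), c(8, 8, 8)),
             array(rnorm(8 * 4 * 4), c(8, 4, 4)))
  pyr <- featurePyramid(lv)
  out <- progressiveFuse(pyr, params)
  expect_equal(lapply(pyramidLevels(out), dim), lapply(lv, dim))
  want <- oracle_progressive_fuse(lv, params)
  for (i in 1:3)
    expect_equal(pyramidLevels(out)[[i]], want[[i]], tolerance = 1e-9)

  # single level degenerates to the top transform
  p1 <- featurePyramid(lv[3])
  params1 <- pfpnParams(8, 1, seed = 35)
  expect_equal(pyramidLevels(progressiveFuse(p1, params1))[[1]],
               topTransform(lv[[3]], params1), tolerance = 1e-10)
})

test_that("fusion is order-sensitive (genuinely progressive)", {
  params <- pfpnParams(8, 2, seed = 37)
  set.seed(38)
  a <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  b <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  out1 <- pyramidLevels(progressiveFuse(featurePyramid(list(a, b)), params))
  # swap content between levels (resized to fit) and check the outputs move
  a2 <- array(as.numeric(a)[1:(8 * 4 * 4)], c(8, 4, 4))
  out2 <- pyramidLevels(progressiveFuse(featurePyramid(list(a, a2)), params))
  expect_gt(max(abs(out1[[1]] - out2[[1]])), 1e-6)
})

test_that("analytic gradients of the full fusion agree with finite differences", {
  err <- checkPfpnGradients(C = 8, shapes = list(c(16, 16), c(8, 8)),
                            probes = 40, seed = 39)
  expect_lt(err, 1e-3)
})

test_that("bilinear upsampling mode is supported and differs from nearest", {
  params <- pfpnParams(8, 2, seed = 40)
  set.seed(41)
  lv <- list(array(rnorm(8 * 9 * 9), c(8, 9, 9)),   # odd sizes
             array(rnorm(8 * 4 * 4), c(8, 4, 4)))
  pyr <- featurePyramid(lv)
  near <- progressiveFuse(pyr, params, "nearest")
  bil <- progressiveFuse(pyr, params, "bilinear")
  expect_equal(dim(pyramidLevels(near)[[1]]), c(8, 9, 9))
  expect_gt(max(abs(pyramidLevels(near)[[1]] - pyramidLevels(bil)[[1]])), 1e-8)
})
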