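#' Miniature end-to-end dense-leaf detector
#'
#' A deliberately small set-based detector that wires the package's
#' components together on CPU: a three-stage convolutional backbone,
#' progressive pyramid fusion, a flatten-to-memory encoder stand-in with
#' fixed sinusoidal positional encodings, learnable queries refined by a
#' small cross-attention decoder emitting one normalized center-form box
#' and one foreground logit per query, crowded query refinement (NMS
#' culling + a Top-K-matched extra branch) and auxiliary-head query
#' injection during training. The novelty under test lives in the fusion,
#' matching and injection strategies; the backbone/encoder/decoder are
#' minimal stand-ins.
#'
#' @slot params nested list of trainable autodiff parameter nodes.
#' @slot config the \code{\link{modelConfig}} list.
#' @exportClass MiniLeafDetr
setClass("MiniLeafDetr", representation(params = "list", config = "list"))

setMethod("show", "MiniLeafDetr", function(object) {
  cfg <- object@config
  np <- sum(vapply(.flatten_params(object@params),
                   function(p) length(p$value), numeric(1)))
  cat(sprintf(
    "MiniLeafDetr: C=%d, %d queries (+%d extra), %d decoder layer(s), %d parameters\n",
    cfg$channels, cfg$nOri, cfg$nExtra, cfg$decoderLayers, np))
  cat(sprintf("  toggles: P-FPN=%s CQR=%s auxHead=%s\n",
              cfg$pfpn, cfg$cqr, cfg$auxHead))
})

#' Model configuration
#'
#' @param channels uniform pyramid/query width C (also the decoder width).
#' @param nOri number of original decoder queries (the query budget used at
#'   inference; dense canopies benefit from several hundred).
#' @param nExtra number of extra-branch queries; defaults to \code{nOri}.
#' @param decoderLayers number of cross-attention decoder layers.
#' @param match a \code{\link{matchConfig}}.
#' @param pfpn,cqr,auxHead ablation toggles for progressive fusion, crowded
#'   query refinement and auxiliary-head injection.
#' @param nmsAtInference apply NMS to inference outputs (off by default;
#'   set-based detectors are end-to-end).
#' @return list of validated settings.
#' @export
modelConfig <- function(channels = 32, nOri = 300, nExtra = nOri,
                        decoderLayers = 1, match = matchConfig(),
                        pfpn = TRUE, cqr = TRUE, auxHead = TRUE,
                        nmsAtInference = FALSE) {
  stopifnot(nOri >= 1, channels %% 8 == 0, decoderLayers >= 1)
  list(channels = as.integer(channels), nOri = as.integer(nOri),
       nExtra = as.integer(nExtra), decoderLayers = as.integer(decoderLayers),
       match = match, pfpn = pfpn, cqr = cqr, auxHead = auxHead,
       nmsAtInference = nmsAtInference)
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: AdamW with initial
#' learning rate 2e-4, weight decay 1e-4, gradient clipping at a max norm
#' of 0.1, 12 epochs with a step decay at epoch 11, and an 8:2
#' train/validation split.
#'
#' @param lr initial learning rate.
#' @param weightDecay decoupled weight decay coefficient.
#' @param clipNorm global gradient-norm clip threshold.
#' @param epochs training epochs (used when \code{iterations} is NULL).
#' @param lrStepEpoch epoch at which the learning rate drops by 10x.
#' @param batchSize scenes per optimisation step.
#' @param seed seed controlling initial weights order-of-use, scene
#'   cycling and auxiliary confidence draws.
#' @param split train fraction of the scenes (rest validates).
#' @param iterations if given, run exactly this many optimisation steps
#'   instead of full epochs.
#' @return list of validated settings.
#' @export
trainConfig <- function(lr = 2e-4, weightDecay = 1e-4, clipNorm = 0.1,
                        epochs = 12, lrStepEpoch = 11, batchSize = 2,
                        seed = 1L, split = 0.8, iterations = NULL) {
  stopifnot(lr > 0, weightDecay >= 0, clipNorm > 0, split > 0, split < 1,
            batchSize >= 1)
  list(lr = lr, weightDecay = weightDecay, clipNorm = clipNorm,
       epochs = as.integer(epochs), lrStepEpoch = as.integer(lrStepEpoch),
       batchSize = as.integer(batchSize), seed = as.integer(seed),
       split = split, iterations = iterations)
}

.lin_p <- function(nin, nout, sd) matrix(stats::rnorm(nin * nout, sd = sd), nin, nout)

.logit <- function(p, eps = 1e-4) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

# Initial reference boxes in logit space: centers uniform over the image,
# sizes around a fifth of the image side.
.ref_boxes <- function(n) {
  cbind(.logit(stats::runif(n, 0.05, 0.95)),
        .logit(stats::runif(n, 0.05, 0.95)),
        .logit(stats::runif(n, 0.1, 0.3)),
        .logit(stats::runif(n, 0.1, 0.3)))
}

#' Build the miniature detector
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed RNG seed for deterministic weight initialisation.
#' @return A \code{\linkS4class{MiniLeafDetr}}.
#' @export
buildModel <- function(config = modelConfig(), seed = 1L) {
  C <- config$channels
  D <- C
  sd0 <- 0.08
  set.seed(seed)
  pf <- pfpnParams(C, 3, seed = seed + 1L, sd = sd0)
  set.seed(seed + 2L)
  params <- list(
    conv0_w = .conv_w(C, 3, 3, sd0), conv0_b = numeric(C),
    conv1_w = .conv_w(C, C, 3, sd0), conv1_b = numeric(C),
    conv2_w = .conv_w(C, C, 3, sd0), conv2_b = numeric(C),
    conv3_w = .conv_w(C, C, 3, sd0), conv3_b = numeric(C),
    pfpn = pf[c("top", "afa")],
    levelEmb = .lin_p(3, D, sd0),
    enc_w = .lin_p(D, D, sd0), enc_b = numeric(D),
    dec = lapply(seq_len(config$decoderLayers), function(l) {
      list(wq = .lin_p(D, D, sd0), wk = .lin_p(D, D, sd0),
           wv = .lin_p(D, D, sd0), wo = .lin_p(D, D, sd0),
           ffn1_w = .lin_p(D, D, sd0), ffn1_b = numeric(D),
           ffn2_w = .lin_p(D, D, sd0), ffn2_b = numeric(D))
    }),
    qOri = .lin_p(config$nOri, D, 0.3),
    qExtra = .lin_p(max(config$nExtra, 1), D, 0.3),
    # per-query reference boxes (logit space), spread over the image so the
    # query set tiles the scene before any training
    qRefOri = .ref_boxes(config$nOri),
    qRefExtra = .ref_boxes(max(config$nExtra, 1)),
    box_w = .lin_p(D, 4, sd0), box_b = numeric(4),
    cls_w = .lin_p(D, 1, sd0),
    cls_b = -2  # background-heavy prior: most queries start negative
  )
  wrapped <- .wrap_params(params, trainable = TRUE)
  new("MiniLeafDetr", params = wrapped, config = config)
}

# Fixed 2-D sinusoidal positional encoding for one level, rows matching
# flattenMemory's column-major spatial order.
.pos_enc_2d <- function(H, W, D) {
  half <- D %/% 2L
  quarter <- half %/% 2L
  freqs <- 10000^(2 * (seq_len(quarter) - 1) / half)
  xs <- (rep(seq_len(W), each = H) - 0.5) / W
  ys <- (rep(seq_len(H), times = W) - 0.5) / H
  enc <- matrix(0, H * W, D)
  for (i in seq_len(quarter)) {
    enc[, 2 * i - 1] <- sin(2 * pi * ys / freqs[i])
    enc[, 2 * i] <- cos(2 * pi * ys / freqs[i])
    enc[, half + 2 * i - 1] <- sin(2 * pi * xs / freqs[i])
    enc[, half + 2 * i] <- cos(2 * pi * xs / freqs[i])
  }
  enc
}

# Backbone + (optional) progressive fusion + memory assembly.
.model_memory <- function(model, image) {
  p <- model@params
  x <- ad_const(aperm(image, c(3, 1, 2)))     # (3,H,W)
  h0 <- ad_avgpool2(ad_relu(ad_conv2d(x, p$conv0_w, p$conv0_b)))
  f1 <- ad_avgpool2(ad_relu(ad_conv2d(h0, p$conv1_w, p$conv1_b)))
  f2 <- ad_avgpool2(ad_relu(ad_conv2d(f1, p$conv2_w, p$conv2_b)))
  f3 <- ad_avgpool2(ad_relu(ad_conv2d(f2, p$conv3_w, p$conv3_b)))
  levels <- list(f1, f2, f3)
  if (model@config$pfpn) levels <- .pfpn_forward_ad(levels, p$pfpn)
  D <- model@config$channels
  mem <- NULL
  shapes <- list()
  for (l in seq_along(levels)) {
    d <- dim(levels[[l]]$value)
    shapes[[l]] <- d
    rows <- ad_flatten_hw(levels[[l]])
    pe <- ad_const(.pos_enc_2d(d[2], d[3], D))
    le <- ad_rows(p$levelEmb, rep(l, d[2] * d[3]))
    rows <- ad_add(ad_add(rows, pe), le)
    mem <- if (is.null(mem)) rows else ad_rbind(mem, rows)
  }
  enc <- ad_add(mem, ad_relu(ad_linear(mem, p$enc_w, p$enc_b)))
  list(memory = enc, shapes = shapes)
}

# Decode a query set against the encoder memory. `ref` holds the queries'
# reference boxes in logit space (learnable for the two branches, fixed to
# the sample box for injected queries); the box head predicts a delta.
.decode_queries <- function(model, queries, memory, ref = NULL) {
  p <- model@params
  D <- model@config$channels
  q <- queries
  for (layer in p$dec) {
    qq <- ad_linear(q, layer$wq)
    kk <- ad_linear(memory, layer$wk)
    vv <- ad_linear(memory, layer$wv)
    att <- ad_softmax_rows(ad_scale(ad_matmul(qq, ad_t(kk)), 1 / sqrt(D)))
    q <- ad_add(q, ad_linear(ad_matmul(att, vv), layer$wo))
    q <- ad_add(q, ad_linear(ad_relu(ad_linear(q, layer$ffn1_w, layer$ffn1_b)),
                             layer$ffn2_w, layer$ffn2_b))
  }
  delta <- ad_linear(q, p$box_w, p$box_b)
  boxes <- ad_sigmoid(if (is.null(ref)) delta else ad_add(delta, ref))
  logits <- ad_add_rowvec(ad_linear(q, p$cls_w), p$cls_b)  # N x 1
  list(boxes = boxes, logits = logits)
}

# GIoU of center-form prediction rows (node) against constant center-form
# ground truths, as an autodiff scalar loss mean(1 - GIoU).
.giou_loss_ad <- function(predBoxes, gtCenter) {
  eps <- 1e-7
  col <- function(x, j) ad_cols(x, j)
  gx <- ad_const(gtCenter)
  px1 <- ad_sub(col(predBoxes, 1), ad_scale(col(predBoxes, 3), 0.5))
  px2 <- ad_add(col(predBoxes, 1), ad_scale(col(predBoxes, 3), 0.5))
  py1 <- ad_sub(col(predBoxes, 2), ad_scale(col(predBoxes, 4), 0.5))
  py2 <- ad_add(col(predBoxes, 2), ad_scale(col(predBoxes, 4), 0.5))
  g1 <- gtCenter[, 1] - gtCenter[, 3] / 2
  g2 <- gtCenter[, 1] + gtCenter[, 3] / 2
  g3 <- gtCenter[, 2] - gtCenter[, 4] / 2
  g4 <- gtCenter[, 2] + gtCenter[, 4] / 2
  cmat <- function(v) ad_const(matrix(v, ncol = 1))
  ix1 <- ad_pmax(px1, cmat(g1)); ix2 <- ad_pmin(px2, cmat(g2))
  iy1 <- ad_pmax(py1, cmat(g3)); iy2 <- ad_pmin(py2, cmat(g4))
  iw <- ad_clamp_min(ad_sub(ix2, ix1), 0)
  ih <- ad_clamp_min(ad_sub(iy2, iy1), 0)
  inter <- ad_mul(iw, ih)
  areap <- ad_mul(ad_clamp_min(ad_sub(px2, px1), 0),
                  ad_clamp_min(ad_sub(py2, py1), 0))
  areag <- cmat((g2 - g1) * (g4 - g3))
  uni <- ad_shift(ad_sub(ad_add(areap, areag), inter), eps)
  iou <- ad_div(inter, uni)
  ex1 <- ad_pmin(px1, cmat(g1)); ex2 <- ad_pmax(px2, cmat(g2))
  ey1 <- ad_pmin(py1, cmat(g3)); ey2 <- ad_pmax(py2, cmat(g4))
  enc <- ad_shift(ad_mul(ad_sub(ex2, ex1), ad_sub(ey2, ey1)), eps)
  giou <- ad_sub(iou, ad_div(ad_sub(enc, uni), enc))
  ad_mean(ad_sub(ad_const(matrix(1, nrow(gtCenter), 1)), giou))
}

# Focal sigmoid classification loss over all logits with 0/1 targets.
.focal_loss_ad <- function(logits, targets, alpha = 0.25, gamma = 2) {
  eps <- 1e-7
  t_ <- ad_const(matrix(targets, ncol = 1))
  p <- ad_sigmoid(logits)
  one_m_p <- ad_shift(ad_neg(p), 1)
  pos <- ad_mul(ad_mul(t_, ad_pow(one_m_p, gamma)),
                ad_neg(ad_log(ad_shift(p, eps))))
  neg <- ad_mul(ad_mul(ad_shift(ad_neg(t_), 1), ad_pow(p, gamma)),
                ad_neg(ad_log(ad_shift(one_m_p, eps))))
  ad_mean(ad_add(ad_scale(pos, alpha), ad_scale(neg, 1 - alpha)))
}

# Branch loss: focal classification over all queries + L1 + GIoU on the
# matched pairs (DETR-family convention).
.branch_loss_ad <- function(out, pairs, gtCenter, wL1 = 5, wGIoU = 2,
                            forcedTargets = NULL) {
  n <- nrow(out$logits$value)
  targets <- numeric(n)
  if (!is.null(forcedTargets)) targets <- forcedTargets
  if (NROW(pairs) > 0) targets[pairs[, "pred"]] <- 1
  loss <- .focal_loss_ad(out$logits, targets)
  if (NROW(pairs) > 0) {
    pb <- ad_rows(out$boxes, pairs[, "pred"])
    gt <- gtCenter[pairs[, "gt"], , drop = FALSE]
    l1 <- ad_mean(ad_abs(ad_sub(pb, ad_const(gt))))
    loss <- ad_add(loss, ad_add(ad_scale(l1, wL1),
                                ad_scale(.giou_loss_ad(pb, gt), wGIoU)))
  }
  loss
}

# One full training forward + loss on a single scene. Returns the loss node
# plus the per-branch assignments (for supervision-coverage accounting).
.train_step_ad <- function(model, scene, auxSeed) {
  cfg <- model@config
  mc <- cfg$match
  img <- sceneImage(scene)
  H <- dim(img)[1]; W <- dim(img)[2]
  gtCorner <- annotateScene(scene)
  gtCenter <- cornerToCenter(gtCorner, W, H)
  mm <- .model_memory(model, img)
  outOri <- .decode_queries(model, model@params$qOri, mm$memory,
                            model@params$qRefOri)
  G <- nrow(gtCorner)
  scoresOri <- as.numeric(1 / (1 + exp(-outOri$logits$value)))
  boxesOri <- outOri$boxes$value

  outExtra <- NULL
  if (cfg$cqr && cfg$nExtra > 0)
    outExtra <- .decode_queries(model, model@params$qExtra, mm$memory,
                                model@params$qRefExtra)

  if (G == 0) {
    loss <- .focal_loss_ad(outOri$logits, numeric(cfg$nOri))
    if (!is.null(outExtra))
      loss <- ad_add(loss, ad_scale(
        .focal_loss_ad(outExtra$logits, numeric(cfg$nExtra)), mc$lambdaExtra))
    return(list(loss = loss, ori = .assignment(NULL, 0),
                extra = .assignment(NULL, 0), injected = integer(0), numGt = 0))
  }

  if (cfg$cqr) {
    comp <- cqrCompose(boxesOri, scoresOri,
                       if (is.null(outExtra)) NULL else outExtra$boxes$value,
                       if (is.null(outExtra)) NULL else
                         as.numeric(1 / (1 + exp(-outExtra$logits$value))),
                       gtCenter, mc)
    aOri <- comp$ori; aExtra <- comp$extra
  } else {
    cost <- buildCostMatrix(boxesOri, scoresOri, gtCenter, mc)
    aOri <- hungarianMatch(cost)
    aExtra <- .assignment(NULL, 0)
  }

  lossOri <- .branch_loss_ad(outOri, assignmentPairs(aOri), gtCenter,
                             mc$wL1, mc$wGIoU)
  lossExtraTotal <- NULL
  if (!is.null(outExtra)) {
    lossExtraTotal <- .branch_loss_ad(outExtra, assignmentPairs(aExtra),
                                      gtCenter, mc$wL1, mc$wGIoU)
  }

  injectedGt <- integer(0)
  if (cfg$auxHead) {
    # adapter + stub head on detached memory values (self-trained branch)
    pyr <- adaptMemory(mm$memory$value, mm$shapes)
    pos <- stubHead(pyr, gtCorner, W, H)
    refined <- jtahRefine(list(pos), seed = auxSeed,
                          nmsThreshold = mc$nmsThreshold)
    if (nrow(refined) > 0) {
      enc <- encodeAsQueries(as.matrix(refined[, c("xmin", "ymin", "xmax", "ymax")]),
                             W, H, dim = cfg$channels)
      outInj <- .decode_queries(model, ad_const(enc$embeddings), mm$memory,
                                ad_const(.logit(enc$referenceBoxes)))
      injPairs <- cbind(pred = seq_len(nrow(refined)), gt = refined$gtIndex)
      lossInj <- .branch_loss_ad(outInj, injPairs, gtCenter, mc$wL1, mc$wGIoU)
      lossExtraTotal <- if (is.null(lossExtraTotal)) lossInj
                        else ad_add(lossExtraTotal, lossInj)
      injectedGt <- refined$gtIndex
    }
  }

  loss <- if (is.null(lossExtraTotal)) lossOri
          else ad_add(lossOri, ad_scale(lossExtraTotal, mc$lambdaExtra))
  list(loss = loss, ori = aOri, extra = aExtra, injected = injectedGt,
       numGt = G)
}

#' Count supervised queries per ground truth
#'
#' Sums, over a list of \code{\link{Assignment}} objects and optionally a
#' vector of directly injected ground-truth indices, how many supervised
#' queries each ground truth receives.
#'
#' @param assignments list of \code{\link{Assignment}}s.
#' @param numGt number of ground truths.
#' @param injectedGt integer vector of ground-truth indices supervised by
#'   injected queries.
#' @return integer vector of per-ground-truth supervised query counts.
#' @export
supervisedPerGt <- function(assignments, numGt, injectedGt = integer(0)) {
  counts <- integer(numGt)
  for (a in assignments) {
    p <- assignmentPairs(a)
    if (nrow(p) > 0) {
      tab <- tabulate(p[, "gt"], nbins = numGt)
      counts <- counts + tab
    }
  }
  if (length(injectedGt) > 0)
    counts <- counts + tabulate(injectedGt, nbins = numGt)
  counts
}

#' Train the miniature detector
#'
#' Seeded, deterministic-per-seed AdamW optimisation with global-norm
#' gradient clipping. Scenes are split into train/validation sets; training
#' cycles the training scenes. Returns the per-iteration combined loss, the
#' final validation \code{\linkS4class{APSummary}}, and supervision
#' coverage bookkeeping. Non-finite losses abort with an explicit
#' divergence error.
#'
#' @param model a \code{\linkS4class{MiniLeafDetr}}.
#' @param scenes list of \code{\linkS4class{LeafScene}} objects (>= 2).
#' @param config a \code{\link{trainConfig}}.
#' @return list with \code{loss} (numeric trajectory), \code{summary}
#'   (validation \code{APSummary}), \code{model}, and \code{coverage}
#'   (mean count of ground truths with >= 2 supervised queries per
#'   iteration).
#' @export
trainModel <- function(model, scenes, config = trainConfig()) {
  stopifnot(length(scenes) >= 2)
  set.seed(config$seed)
  n <- length(scenes)
  ntrain <- max(1, round(config$split * n))
  idx <- sample.int(n)
  train_idx <- idx[seq_len(ntrain)]
  val_idx <- if (ntrain < n) idx[(ntrain + 1):n] else idx[seq_len(min(2, n))]

  params <- .flatten_params(model@params)
  state <- adamw_state(params)
  iters_per_epoch <- max(1L, ceiling(ntrain / config$batchSize))
  total_iters <- if (!is.null(config$iterations)) as.integer(config$iterations)
                 else config$epochs * iters_per_epoch
  losses <- numeric(total_iters)
  cover2 <- numeric(total_iters)
  cursor <- 0L
  for (it in seq_len(total_iters)) {
    epoch <- ((it - 1L) %/% iters_per_epoch) + 1L
    lr <- if (epoch >= config$lrStepEpoch) config$lr * 0.1 else config$lr
    ad_zero_grads(params)
    batch_loss <- 0
    batch_cover <- 0
    for (b in seq_len(config$batchSize)) {
      cursor <- (cursor %% ntrain) + 1L
      sc <- scenes[[train_idx[cursor]]]
      aux_seed <- sample.int(2^30, 1)
      step <- .train_step_ad(model, sc, aux_seed)
      if (!is.finite(step$loss$value))
        stop("training diverged: non-finite loss at iteration ", it)
      scaled <- ad_scale(step$loss, 1 / config$batchSize)
      ad_backward(scaled)
      batch_loss <- batch_loss + step$loss$value / config$batchSize
      if (step$numGt > 0) {
        cov <- supervisedPerGt(list(step$ori, step$extra), step$numGt,
                               step$injected)
        batch_cover <- batch_cover + sum(cov >= 2) / config$batchSize
      }
    }
    state <- adamw_step(params, state, lr = lr,
                        weight_decay = config$weightDecay,
                        clip_norm = config$clipNorm)
    losses[it] <- batch_loss
    cover2[it] <- batch_cover
  }

  dets <- list(); gts <- list()
  for (v in seq_along(val_idx)) {
    sc <- scenes[[val_idx[v]]]
    id <- as.character(v)
    r <- inferBoxes(model, sceneImage(sc), scoreThreshold = 0)
    dets[[id]] <- r
    gts[[id]] <- list(boxes = annotateScene(sc))
  }
  summary <- evaluateDetections(dets, gts)
  list(loss = losses, summary = summary, model = model,
       coverage = mean(cover2))
}

#' Decode both query branches of the detector on one image
#'
#' Training-time view of the decoder: returns the original and (when CQR is
#' enabled) extra branch outputs as normalized center-form boxes with
#' foreground probabilities, without thresholding or NMS. Used to study
#' matching behaviour; inference proper goes through
#' \code{\link{inferBoxes}}.
#'
#' @param model a \code{\linkS4class{MiniLeafDetr}}.
#' @param image \code{(H, W, 3)} array.
#' @return list with \code{ori} and \code{extra}, each a list of
#'   \code{boxes} (normalized center form) and \code{scores}
#'   (\code{extra} is NULL when CQR is off).
#' @export
modelQueries <- function(model, image) {
  mm <- .model_memory(model, image)
  outOri <- .decode_queries(model, model@params$qOri, mm$memory,
                            model@params$qRefOri)
  ori <- list(boxes = outOri$boxes$value,
              scores = as.numeric(1 / (1 + exp(-outOri$logits$value))))
  extra <- NULL
  if (model@config$cqr && model@config$nExtra > 0) {
    outExtra <- .decode_queries(model, model@params$qExtra, mm$memory,
                                model@params$qRefExtra)
    extra <- list(boxes = outExtra$boxes$value,
                  scores = as.numeric(1 / (1 + exp(-outExtra$logits$value))))
  }
  list(ori = ori, extra = extra)
}

#' Run inference with the miniature detector
#'
#' Evaluation mode: only the original-branch queries are decoded (the extra
#' branch and auxiliary injection are training-time devices), scores are
#' sigmoid foreground probabilities, and no NMS is applied unless
#' requested.
#'
#' @param model a \code{\linkS4class{MiniLeafDetr}}.
#' @param image \code{(H, W, 3)} array.
#' @param scoreThreshold drop detections below this score.
#' @param nms apply class-agnostic NMS to the outputs.
#' @param nmsThreshold IoU threshold when \code{nms} is TRUE.
#' @return list with \code{boxes} (corner form, absolute pixels) and
#'   \code{scores}.
#' @export
inferBoxes <- function(model, image, scoreThreshold = 0.5,
                       nms = model@config$nmsAtInference,
                       nmsThreshold = model@config$match$nmsThreshold) {
  H <- dim(image)[1]; W <- dim(image)[2]
  mm <- .model_memory(model, image)
  out <- .decode_queries(model, model@params$qOri, mm$memory,
                         model@params$qRefOri)
  scores <- as.numeric(1 / (1 + exp(-out$logits$value)))
  boxes <- centerToCorner(out$boxes$value, W, H)
  keep <- which(scores >= scoreThreshold)
  boxes <- boxes[keep, , drop = FALSE]
  scores <- scores[keep]
  if (nms && length(scores) > 0) {
    ki <- classAgnosticNMS(boxes, scores, nmsThreshold)
    boxes <- boxes[ki, , drop = FALSE]
    scores <- scores[ki]
  }
  list(boxes = boxes, scores = scores)
}
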