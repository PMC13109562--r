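#' Flatten a feature pyramid into encoder memory
#'
#' The encoder consumes the pyramid as a flat sequence: each level's
#' \code{(C,H,W)} grid becomes \code{H*W} rows of a \code{(sum H*W) x C}
#' matrix (spatial positions in R's column-major order), levels stacked in
#' order. The level shapes are attached so the operation is invertible.
#'
#' @param pyramid a \code{\linkS4class{FeaturePyramid}}.
#' @return list with \code{memory} (L x C matrix) and \code{shapes} (list
#'   of level dims).
#' @export
flattenMemory <- function(pyramid) {
  lv <- pyramidLevels(pyramid)
  mats <- lapply(lv, function(x) {
    d <- dim(x)
    m <- x
    dim(m) <- c(d[1], d[2] * d[3])
    t(m)
  })
  list(memory = do.call(rbind, mats), shapes = lapply(lv, dim))
}

#' Unflatten encoder memory back into a pyramid
#'
#' Exact inverse of \code{\link{flattenMemory}}:
#' \code{adaptMemory(flattenMemory(p)$memory, shapes)} reproduces p
#' bit-identically. This is the adapter that feeds auxiliary detection
#' heads from the encoder output.
#'
#' @param memory L x C matrix.
#' @param shapes list of \code{c(C, H, W)} level dims.
#' @return A \code{\linkS4class{FeaturePyramid}}.
#' @export
adaptMemory <- function(memory, shapes) {
  lens <- vapply(shapes, function(d) d[2] * d[3], numeric(1))
  if (nrow(memory) != sum(lens))
    stop("memory length does not match the level shapes")
  offset <- 0L
  levels <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    d <- shapes[[i]]
    block <- memory[(offset + 1):(offset + lens[i]), , drop = FALSE]
    x <- t(block)
    dim(x) <- d
    levels[[i]] <- x
    offset <- offset + lens[i]
  }
  featurePyramid(levels)
}

#' Stub auxiliary detection head
#'
#' A desk-scale stand-in for a conventional (one/two-stage) auxiliary head:
#' it proposes jittered anchors around the strongest activation peaks of
#' the highest-resolution feature level and keeps every proposal whose IoU
#' with some ground truth reaches \code{iouAccept}. Several proposals may
#' hit the same ground truth, so the label-assignment rule is one-to-many
#' by construction. Randomness (jitter) comes from the current RNG stream.
#'
#' @param features a \code{\linkS4class{FeaturePyramid}}.
#' @param gtBoxes ground-truth boxes, corner form, absolute pixels.
#' @param imageWidth,imageHeight image size corresponding to the pyramid.
#' @param iouAccept acceptance IoU against the best ground truth.
#' @param nPeaks number of activation peaks to seed anchors at.
#' @param proposalsPerPeak anchors proposed per peak.
#' @param jitterSd center jitter, as a fraction of the anchor size.
#' @return box matrix (corner form) of accepted proposals; the matched
#'   ground-truth index of each as attribute \code{"gtIndex"}.
#' @export
stubHead <- function(features, gtBoxes, imageWidth, imageHeight,
                     iouAccept = 0.5, nPeaks = 20, proposalsPerPeak = 3,
                     jitterSd = 0.1) {
  empty <- leafBoxes(numeric(0), numeric(0), numeric(0), numeric(0))
  attr(empty, "gtIndex") <- integer(0)
  if (NROW(gtBoxes) == 0) return(empty)
  gtBoxes <- .as_box_matrix(gtBoxes)
  lv <- pyramidLevels(features)[[1]]
  d <- dim(lv)
  act <- apply(abs(lv), c(2, 3), mean)          # H x W activation map
  strideY <- imageHeight / d[2]
  strideX <- imageWidth / d[3]
  ord <- order(-as.numeric(act))[seq_len(min(nPeaks, length(act)))]
  pr <- ((ord - 1) %% d[2]) + 1                 # row (y) index
  pc <- ((ord - 1) %/% d[2]) + 1                # col (x) index
  cxs <- (pc - 0.5) * strideX
  cys <- (pr - 0.5) * strideY
  # anchor scale from the ground-truth size statistics (the stand-in for a
  # trained head's learned scale prior)
  bw <- stats::median(gtBoxes[, 3] - gtBoxes[, 1])
  bh <- stats::median(gtBoxes[, 4] - gtBoxes[, 2])
  props <- NULL
  for (i in seq_along(ord)) {
    for (p in seq_len(proposalsPerPeak)) {
      s <- stats::runif(1, 0.8, 1.25)
      w <- bw * s; h <- bh * s
      cx <- cxs[i] + stats::rnorm(1, sd = jitterSd * w)
      cy <- cys[i] + stats::rnorm(1, sd = jitterSd * h)
      props <- rbind(props, c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2))
    }
  }
  iou <- boxIoU(props, gtBoxes)
  best <- max.col(iou, ties.method = "first")
  bestIou <- iou[cbind(seq_len(nrow(iou)), best)]
  keep <- which(bestIou >= iouAccept)
  if (length(keep) == 0) return(empty)
  out <- leafBoxes(props[keep, 1], props[keep, 2], props[keep, 3], props[keep, 4])
  attr(out, "gtIndex") <- best[keep]
  out
}

#' Randomized-confidence refinement of auxiliary positives
#'
#' Concatenates the positive boxes of all auxiliary heads, discards the
#' heads' own confidences entirely and draws fresh i.i.d. scores from
#' U(0,1) under the given seed, then suppresses overlaps with
#' class-agnostic NMS on those randomized scores. Survivors are therefore
#' pairwise non-overlapping above the threshold, and which of two mutually
#' exclusive boxes survives is decided by the random draw, never by the
#' heads. Deterministic for a fixed seed.
#'
#' @param posLists list of box matrices (corner form), one per head.
#' @param seed RNG seed for the confidence draw.
#' @param nmsThreshold suppression IoU threshold.
#' @return data.frame with box coordinates, \code{assignedConfidence},
#'   \code{sourceHead} and (when the inputs carry a \code{"gtIndex"}
#'   attribute) \code{gtIndex}, in descending confidence order.
#' @export
jtahRefine <- function(posLists, seed = 1L, nmsThreshold = 0.7) {
  boxes <- NULL
  head_id <- integer(0)
  gt_idx <- integer(0)
  for (h in seq_along(posLists)) {
    b <- posLists[[h]]
    if (NROW(b) == 0) next
    b <- .as_box_matrix(b)
    boxes <- rbind(boxes, b[, 1:4, drop = FALSE])
    head_id <- c(head_id, rep(h, nrow(b)))
    gi <- attr(posLists[[h]], "gtIndex")
    gt_idx <- c(gt_idx, if (is.null(gi)) rep(NA_integer_, nrow(b)) else gi)
  }
  if (is.null(boxes)) {
    return(data.frame(xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0),
                      assignedConfidence = numeric(0),
                      sourceHead = integer(0), gtIndex = integer(0)))
  }
  set.seed(seed)
  conf <- stats::runif(nrow(boxes))
  keep <- classAgnosticNMS(boxes, conf, nmsThreshold)
  data.frame(xmin = boxes[keep, 1], ymin = boxes[keep, 2],
             xmax = boxes[keep, 3], ymax = boxes[keep, 4],
             assignedConfidence = conf[keep], sourceHead = head_id[keep],
             gtIndex = gt_idx[keep])
}

#' Sinusoidal query encoding of positive samples
#'
#' Each box is converted to normalized center form \code{(cx, cy, w, h)}
#' and each of the four coordinates t is expanded into \code{dim/4}
#' sinusoidal features: with \code{d = dim/4} and
#' \code{freq_i = 10000^(2i/d)} for \code{i = 0, ..., d/2 - 1}, the
#' features are \code{sin(2*pi*t/freq_i)} and \code{cos(2*pi*t/freq_i)},
#' interleaved. The embedding is a fixed function of the box, so identical
#' boxes map to identical embeddings.
#'
#' @param boxes box matrix, corner form, absolute pixels.
#' @param imageWidth,imageHeight image size for normalization.
#' @param dim embedding dimension; must be a multiple of 8.
#' @return list with \code{embeddings} (m x dim matrix) and
#'   \code{referenceBoxes} (m x 4, normalized center form).
#' @export
encodeAsQueries <- function(boxes, imageWidth, imageHeight, dim = 32) {
  if (dim %% 8 != 0) stop("dim must be a multiple of 8")
  b <- .as_box_matrix(boxes)
  if (nrow(b) == 0) {
    return(list(embeddings = matrix(numeric(0), 0, dim),
                referenceBoxes = matrix(numeric(0), 0, 4)))
  }
  cb <- cornerToCenter(b, imageWidth, imageHeight)
  d4 <- dim %/% 4L
  half <- d4 %/% 2L
  freqs <- 10000^(2 * (seq_len(half) - 1) / d4)
  emb <- matrix(0, nrow(cb), dim)
  for (j in seq_len(4)) {
    t_ <- cb[, j]
    block <- matrix(0, nrow(cb), d4)
    for (i in seq_len(half)) {
      block[, 2 * i - 1] <- sin(2 * pi * t_ / freqs[i])
      block[, 2 * i] <- cos(2 * pi * t_ / freqs[i])
    }
    emb[, ((j - 1) * d4 + 1):(j * d4)] <- block
  }
  list(embeddings = emb, referenceBoxes = cb)
}
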