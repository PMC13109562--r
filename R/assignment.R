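#' @import methods
NULL

#' Assignment between predictions and ground truths
#'
#' Result container for one-to-one Hungarian matching and its Top-K
#' one-to-many variant. \code{pairs} is an integer matrix with columns
#' \code{pred} and \code{gt} (1-based row indices into the matched sets);
#' each prediction appears at most once, while a ground truth may appear up
#' to k times in Top-K mode.
#'
#' @slot pairs integer matrix with columns \code{pred}, \code{gt}.
#' @slot totalCost numeric, the summed cost over the pairs.
#' @exportClass Assignment
setClass("Assignment",
         representation(pairs = "matrix", totalCost = "numeric"),
         validity = function(object) {
           p <- object@pairs
           if (nrow(p) > 0 && anyDuplicated(p[, "pred"]))
             return("each prediction may be assigned at most once")
           TRUE
         })

.assignment <- function(pairs, totalCost) {
  if (is.null(pairs) || nrow(pairs) == 0)
    pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("pred", "gt")))
  colnames(pairs) <- c("pred", "gt")
  rownames(pairs) <- NULL
  storage.mode(pairs) <- "integer"
  new("Assignment", pairs = pairs, totalCost = as.numeric(totalCost))
}

#' @describeIn Assignment matched (prediction, ground-truth) index pairs.
#' @param object an \code{Assignment}.
#' @export
setGeneric("assignmentPairs", function(object) standardGeneric("assignmentPairs"))

#' @rdname Assignment-class
#' @export
setMethod("assignmentPairs", "Assignment", function(object) object@pairs)

#' @describeIn Assignment total matching cost.
#' @export
setGeneric("totalCost", function(object) standardGeneric("totalCost"))

#' @rdname Assignment-class
#' @export
setMethod("totalCost", "Assignment", function(object) object@totalCost)

setMethod("show", "Assignment", function(object) {
  cat("Assignment with", nrow(object@pairs), "pair(s), total cost",
      format(object@totalCost, digits = 6), "\n")
  if (nrow(object@pairs) > 0) {
    n <- min(nrow(object@pairs), 8L)
    for (i in seq_len(n))
      cat(sprintf("  pred %d -> gt %d\n", object@pairs[i, 1], object@pairs[i, 2]))
    if (nrow(object@pairs) > n) cat("  ...\n")
  }
})

#' Matching configuration for crowded query refinement
#'
#' @param k number of replicas per ground truth in Top-K Hungarian matching
#'   (1-8); default 4, the value at which the replica sweep peaks.
#' @param nmsThreshold IoU threshold for the class-agnostic NMS applied to
#'   original queries before one-to-one matching.
#' @param lambdaExtra weight of the extra-branch loss; the one-to-many branch
#'   is supervised at a lower weight than the original branch.
#' @param wCls,wL1,wGIoU matching cost component weights (DETR-family
#'   convention: cost = wCls*(1-p) + wL1*L1 + wGIoU*(1-GIoU)).
#' @return A list of validated settings.
#' @export
matchConfig <- function(k = 4, nmsThreshold = 0.7, lambdaExtra = 0.5,
                        wCls = 2, wL1 = 5, wGIoU = 2) {
  stopifnot(k >= 1, k == round(k), nmsThreshold > 0, nmsThreshold <= 1,
            lambdaExtra >= 0)
  list(k = as.integer(k), nmsThreshold = nmsThreshold,
       lambdaExtra = lambdaExtra, wCls = wCls, wL1 = wL1, wGIoU = wGIoU)
}

#' Build a prediction-to-ground-truth cost matrix
#'
#' DETR-convention matching cost for each (prediction, ground truth) pair:
#' \code{wCls*(1 - p) + wL1*L1(center-form boxes) + wGIoU*(1 - GIoU)}, where
#' p is the prediction's foreground class probability and L1 is the mean
#' absolute difference of the normalized \code{(cx,cy,w,h)} coordinates.
#'
#' @param predBoxes prediction boxes, normalized center form (P x 4).
#' @param predProbs foreground class probabilities, length P.
#' @param gtBoxes ground-truth boxes, normalized center form (G x 4); may
#'   have zero rows.
#' @param config a \code{\link{matchConfig}}.
#' @return P x G numeric cost matrix (0 columns when G = 0).
#' @export
buildCostMatrix <- function(predBoxes, predProbs, gtBoxes,
                            config = matchConfig()) {
  predBoxes <- .as_box_matrix(predBoxes)
  P <- nrow(predBoxes)
  if (P == 0) stop("prediction set must be nonempty")
  if (length(predProbs) != P) stop("boxes/scores dimension mismatch")
  if (is.null(gtBoxes) || NROW(gtBoxes) == 0)
    return(matrix(numeric(0), P, 0))
  gtBoxes <- .as_box_matrix(gtBoxes)
  G <- nrow(gtBoxes)
  l1 <- matrix(0, P, G)
  for (j in seq_len(4)) {
    l1 <- l1 + abs(outer(predBoxes[, j], gtBoxes[, j], "-"))
  }
  l1 <- l1 / 4
  pc <- .center_to_corner_unit(predBoxes)
  gc_ <- .center_to_corner_unit(gtBoxes)
  giou <- boxGIoU(pc, gc_)
  cost <- config$wCls * (1 - predProbs) + config$wL1 * l1 +
    config$wGIoU * (1 - giou)
  matrix(cost, P, G)
}

.center_to_corner_unit <- function(cb) {
  cbind(cb[, 1] - cb[, 3] / 2, cb[, 2] - cb[, 4] / 2,
        cb[, 1] + cb[, 3] / 2, cb[, 2] + cb[, 4] / 2)
}

#' One-to-one Hungarian matching
#'
#' Minimum-cost one-to-one assignment of min(P, G) pairs. Rectangular
#' matrices are zero-padded to square so that every real row/column of the
#' smaller side is used; the solve itself is delegated to
#' \code{clue::solve_LSAP}.
#'
#' @param cost P x G numeric cost matrix with finite entries.
#' @return An \code{\link{Assignment}}.
#' @examples
#' hungarianMatch(matrix(c(1, 2, 2, 1), 2, 2))
#' @export
hungarianMatch <- function(cost) {
  cost <- as.matrix(cost)
  P <- nrow(cost); G <- ncol(cost)
  if (P == 0 || G == 0) return(.assignment(NULL, 0))
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  n <- max(P, G)
  sq <- matrix(0, n, n)
  shift <- min(cost, 0)
  sq[seq_len(P), seq_len(G)] <- cost - shift  # solve_LSAP wants nonnegative
  sol <- clue::solve_LSAP(sq)
  pred <- seq_len(P)
  gt <- as.integer(sol)[seq_len(P)]
  keep <- gt <= G
  pairs <- cbind(pred = pred[keep], gt = gt[keep])
  .assignment(pairs, sum(cost[pairs]))
}

#' Top-K Hungarian one-to-many matching
#'
#' Replicates each ground truth k times: round r runs one-to-one Hungarian
#' matching on the predictions not yet assigned in rounds 1..r-1, so a
#' ground truth collects up to k distinct predictions and
#' \code{nrow(pairs) = min(k*G, P)}. With \code{k = 1} this is exactly
#' \code{\link{hungarianMatch}}.
#'
#' @inheritParams hungarianMatch
#' @param k number of replicas per ground truth (>= 1).
#' @return An \code{\link{Assignment}} in which each ground-truth index
#'   appears at most k times.
#' @export
topkHungarianMatch <- function(cost, k = 4) {
  stopifnot(k >= 1, k == round(k))
  cost <- as.matrix(cost)
  P <- nrow(cost); G <- ncol(cost)
  if (P == 0 || G == 0) return(.assignment(NULL, 0))
  pool <- seq_len(P)
  pairs <- NULL
  total <- 0
  for (r in seq_len(k)) {
    if (length(pool) == 0) break
    sub <- cost[pool, , drop = FALSE]
    a <- hungarianMatch(sub)
    ap <- assignmentPairs(a)
    if (nrow(ap) == 0) break
    pairs <- rbind(pairs, cbind(pred = pool[ap[, "pred"]], gt = ap[, "gt"]))
    total <- total + totalCost(a)
    pool <- setdiff(pool, pool[ap[, "pred"]])
  }
  .assignment(pairs, total)
}

#' Compose the crowded-query-refinement matching
#'
#' Original queries are first culled by class-agnostic NMS on their scores,
#' then matched one-to-one by Hungarian matching (indices reported against
#' the original, un-culled list). Extra queries skip NMS: they are ranked by
#' classification score and matched one-to-many by Top-K Hungarian matching.
#' With no extra queries the result reduces to NMS + one-to-one matching.
#'
#' @param oriBoxes,oriProbs original-branch query boxes (normalized center
#'   form, P x 4) and foreground probabilities.
#' @param extraBoxes,extraProbs extra-branch queries; may be NULL/empty.
#' @param gtBoxes ground-truth boxes, normalized center form.
#' @param config a \code{\link{matchConfig}}.
#' @return list with elements \code{ori} and \code{extra}
#'   (\code{\link{Assignment}} objects; \code{extra} has zero pairs when the
#'   extra branch is empty) and \code{keptOri}, the NMS-surviving original
#'   indices.
#' @export
cqrCompose <- function(oriBoxes, oriProbs, extraBoxes, extraProbs, gtBoxes,
                       config = matchConfig()) {
  oriBoxes <- .as_box_matrix(oriBoxes)
  corner <- .center_to_corner_unit(oriBoxes)
  kept <- classAgnosticNMS(corner, oriProbs, config$nmsThreshold)
  costOri <- buildCostMatrix(oriBoxes[kept, , drop = FALSE], oriProbs[kept],
                             gtBoxes, config)
  aOri <- hungarianMatch(costOri)
  pOri <- assignmentPairs(aOri)
  if (nrow(pOri) > 0) pOri[, "pred"] <- kept[pOri[, "pred"]]
  aOri <- .assignment(pOri, totalCost(aOri))

  if (is.null(extraBoxes) || NROW(extraBoxes) == 0) {
    aExtra <- .assignment(NULL, 0)
  } else {
    extraBoxes <- .as_box_matrix(extraBoxes)
    ord <- order(-extraProbs, seq_along(extraProbs))  # rank by class score
    costExtra <- buildCostMatrix(extraBoxes[ord, , drop = FALSE],
                                 extraProbs[ord], gtBoxes, config)
    aExtra <- topkHungarianMatch(costExtra, config$k)
    pExtra <- assignmentPairs(aExtra)
    if (nrow(pExtra) > 0) pExtra[, "pred"] <- ord[pExtra[, "pred"]]
    aExtra <- .assignment(pExtra, totalCost(aExtra))
  }
  list(ori = aOri, extra = aExtra, keptOri = kept)
}

#' Combine original and extra branch losses
#'
#' The one-to-many extra branch is supervised under a lower weight:
#' \code{lossOri + lambdaExtra * lossExtra}.
#'
#' @param lossOri,lossExtra nonnegative branch losses.
#' @param lambdaExtra extra-branch weight, >= 0.
#' @return numeric scalar.
#' @export
combinedLoss <- function(lossOri, lossExtra, lambdaExtra = 0.5) {
  if (lambdaExtra < 0) stop("lambdaExtra must be nonnegative")
  stopifnot(lossOri >= 0, lossExtra >= 0)
  lossOri + lambdaExtra * lossExtra
}
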