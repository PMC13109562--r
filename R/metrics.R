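#' COCO-style detection evaluation summary
#'
#' All values are proportions in [0, 1]. \code{mAP} averages AP over the
#' IoU grid 0.50:0.05:0.95; \code{mAP50}/\code{mAP75} fix the threshold;
#' \code{AR100}/\code{AR300} are average recall with at most 100/300
#' detections per image, averaged over the same IoU grid. Precision, recall
#' and F1 are computed at IoU 0.5 with a configurable score threshold.
#'
#' @slot mAP,mAP50,mAP75,AR100,AR300,precision,recall,F1 numeric scalars.
#' @exportClass APSummary
setClass("APSummary",
         representation(mAP = "numeric", mAP50 = "numeric", mAP75 = "numeric",
                        AR100 = "numeric", AR300 = "numeric",
                        precision = "numeric", recall = "numeric",
                        F1 = "numeric"),
         validity = function(object) {
           v <- c(object@mAP, object@mAP50, object@mAP75, object@AR100,
                  object@AR300, object@precision, object@recall, object@F1)
           if (any(v < -1e-12 | v > 1 + 1e-12)) return("metrics must lie in [0,1]")
           if (object@AR300 < object@AR100 - 1e-12)
             return("AR@300 cannot be below AR@100")
           TRUE
         })

setMethod("show", "APSummary", function(object) {
  cat(sprintf(
    "APSummary: mAP %.1f%% | mAP@50 %.1f%% | mAP@75 %.1f%% | AR@100 %.1f%% | AR@300 %.1f%%\n",
    100 * object@mAP, 100 * object@mAP50, 100 * object@mAP75,
    100 * object@AR100, 100 * object@AR300))
  cat(sprintf("           precision %.3f | recall %.3f | F1 %.3f\n",
              object@precision, object@recall, object@F1))
})

#' @describeIn APSummary extract all metrics as a named numeric vector.
#' @param object an \code{APSummary}.
#' @export
setGeneric("metricValues", function(object) standardGeneric("metricValues"))

#' @rdname APSummary-class
#' @export
setMethod("metricValues", "APSummary", function(object) {
  c(mAP = object@mAP, mAP50 = object@mAP50, mAP75 = object@mAP75,
    AR100 = object@AR100, AR300 = object@AR300,
    precision = object@precision, recall = object@recall, F1 = object@F1)
})

.coco_iou_grid <- seq(0.5, 0.95, by = 0.05)

#' Greedy detection-to-ground-truth matching
#'
#' COCO convention: detections are processed in descending score order (ties
#' broken by original index); each is matched to the unmatched ground truth
#' of highest IoU, and flagged TP iff that IoU reaches the threshold. Each
#' ground truth is matched at most once.
#'
#' @param detBoxes detection boxes (corner form, n x 4).
#' @param detScores detection scores, length n.
#' @param gtBoxes ground-truth boxes (corner form).
#' @param iouThreshold IoU needed for a true positive.
#' @param maxDets keep only this many highest-scoring detections.
#' @return list with \code{tp} (logical flags in ranked order), \code{order}
#'   (the ranked original indices), and \code{fn} (unmatched ground truths).
#' @export
greedyMatch <- function(detBoxes, detScores, gtBoxes, iouThreshold = 0.5,
                        maxDets = Inf) {
  n <- length(detScores)
  ord <- order(-detScores, seq_len(n))
  if (is.finite(maxDets) && length(ord) > maxDets) ord <- ord[seq_len(maxDets)]
  G <- NROW(gtBoxes)
  tp <- logical(length(ord))
  if (G == 0 || length(ord) == 0)
    return(list(tp = tp, order = ord, fn = G))
  iou <- boxIoU(.as_box_matrix(detBoxes)[ord, , drop = FALSE],
                .as_box_matrix(gtBoxes))
  taken <- logical(G)
  for (i in seq_along(ord)) {
    avail <- which(!taken)
    if (length(avail) == 0) break
    j <- avail[which.max(iou[i, avail])]
    if (iou[i, j] >= iouThreshold) {
      tp[i] <- TRUE
      taken[j] <- TRUE
    }
  }
  list(tp = tp, order = ord, fn = sum(!taken))
}

#' Average precision from ranked TP/FP flags
#'
#' 101-point interpolated AP (the COCO dialect): precision is replaced by
#' its running maximum over recall >= r and sampled at
#' r in 0, 0.01, ..., 1.00. \code{mode = "auc"} instead integrates the raw
#' precision-recall curve (the literal area-under-curve reading).
#'
#' @param flags logical vector, TRUE for TP, in descending score order.
#' @param numGt number of ground-truth objects; AP is 0 when no ground
#'   truth exists but detections do.
#' @param mode \code{"101pt"} (default) or \code{"auc"}.
#' @return AP in [0,1].
#' @examples
#' apFromRankedFlags(c(TRUE, FALSE, TRUE), 2)  # (51 + 50 * 2/3) / 101
#' @export
apFromRankedFlags <- function(flags, numGt, mode = c("101pt", "auc")) {
  mode <- match.arg(mode)
  if (numGt == 0) return(0)
  if (length(flags) == 0) return(0)
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  prec <- tp / (tp + fp)
  rec <- tp / numGt
  if (mode == "101pt") {
    rgrid <- seq(0, 1, by = 0.01)
    # envelope: best precision at recall >= r
    env <- rev(cummax(rev(prec)))
    ap <- vapply(rgrid, function(r) {
      i <- which(rec >= r - 1e-12)
      if (length(i) == 0) 0 else env[i[1]]
    }, numeric(1))
    mean(ap)
  } else {
    # trapezoid-free exact integral of the step PR curve over recall
    r_prev <- 0
    area <- 0
    for (i in seq_along(rec)) {
      if (rec[i] > r_prev) {
        area <- area + (rec[i] - r_prev) * prec[i]
        r_prev <- rec[i]
      }
    }
    area
  }
}

# Dataset-level AP at one IoU threshold: per-image greedy matching, then a
# global score ranking of all detections with their TP flags.
.dataset_ap <- function(dets, gts, iouThreshold, maxDets = 100) {
  all_scores <- numeric(0)
  all_tp <- logical(0)
  num_gt <- 0
  for (id in names(gts)) {
    g <- gts[[id]]
    d <- dets[[id]]
    num_gt <- num_gt + NROW(g$boxes)
    if (is.null(d) || length(d$scores) == 0) next
    m <- greedyMatch(d$boxes, d$scores, g$boxes, iouThreshold, maxDets)
    all_scores <- c(all_scores, d$scores[m$order])
    all_tp <- c(all_tp, m$tp)
  }
  if (length(all_scores) == 0) return(if (num_gt > 0) 0 else NA_real_)
  ord <- order(-all_scores)
  apFromRankedFlags(all_tp[ord], num_gt)
}

.dataset_recall <- function(dets, gts, iouThreshold, maxDets) {
  matched <- 0
  num_gt <- 0
  for (id in names(gts)) {
    g <- gts[[id]]
    G <- NROW(g$boxes)
    num_gt <- num_gt + G
    d <- dets[[id]]
    if (is.null(d) || length(d$scores) == 0 || G == 0) next
    m <- greedyMatch(d$boxes, d$scores, g$boxes, iouThreshold, maxDets)
    matched <- matched + (G - m$fn)
  }
  if (num_gt == 0) return(NA_real_)
  matched / num_gt
}

#' Summarize detections against ground truth
#'
#' Computes the COCO-style summary used throughout the evaluation tables:
#' mAP over IoU 0.50:0.05:0.95, mAP@50, mAP@75, AR@100 and AR@300, plus
#' precision/recall/F1 at IoU 0.5 for detections above a score threshold.
#' There is a single foreground category (leaf), so the class average is
#' over one class.
#'
#' @param detections named list (by image id); each element a list with
#'   \code{boxes} (corner form) and \code{scores}.
#' @param groundTruths named list (by image id); each element a list with
#'   \code{boxes}.
#' @param scoreThreshold threshold for the standalone precision/recall/F1.
#' @return An \code{\linkS4class{APSummary}}.
#' @export
evaluateDetections <- function(detections, groundTruths, scoreThreshold = 0.5) {
  unknown <- setdiff(names(detections), names(groundTruths))
  if (length(unknown) > 0)
    stop("detections reference unknown image id(s): ",
         paste(unknown, collapse = ", "))
  aps <- vapply(.coco_iou_grid, function(t)
    .dataset_ap(detections, groundTruths, t, maxDets = 100), numeric(1))
  ars100 <- vapply(.coco_iou_grid, function(t)
    .dataset_recall(detections, groundTruths, t, maxDets = 100), numeric(1))
  ars300 <- vapply(.coco_iou_grid, function(t)
    .dataset_recall(detections, groundTruths, t, maxDets = 300), numeric(1))

  tp <- 0; fp <- 0; fn <- 0
  for (id in names(groundTruths)) {
    g <- groundTruths[[id]]
    d <- detections[[id]]
    if (is.null(d) || length(d$scores) == 0) {
      fn <- fn + NROW(g$boxes)
      next
    }
    keep <- d$scores >= scoreThreshold
    if (!any(keep)) {
      fn <- fn + NROW(g$boxes)
      next
    }
    m <- greedyMatch(.as_box_matrix(d$boxes)[keep, , drop = FALSE],
                     d$scores[keep], g$boxes, 0.5)
    tp <- tp + sum(m$tp)
    fp <- fp + sum(!m$tp)
    fn <- fn + m$fn
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0

  zero_if_nan <- function(x) if (all(is.na(x))) 0 else mean(x, na.rm = TRUE)
  new("APSummary",
      mAP = zero_if_nan(aps), mAP50 = if (is.na(aps[1])) 0 else aps[1],
      mAP75 = if (is.na(aps[6])) 0 else aps[6],
      AR100 = zero_if_nan(ars100), AR300 = zero_if_nan(ars300),
      precision = precision, recall = recall, F1 = f1)
}

#' Write an APSummary as JSON and a text table
#'
#' @param summary an \code{\linkS4class{APSummary}}.
#' @param jsonPath,tablePath output paths; either may be NULL to skip.
#' @return the summary, invisibly.
#' @export
writeSummary <- function(summary, jsonPath = NULL, tablePath = NULL) {
  vals <- as.list(metricValues(summary))
  if (!is.null(jsonPath))
    jsonlite::write_json(vals, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(tablePath)) {
    hdr <- c("mAP", "mAP@50", "mAP@75", "AR@100", "AR@300")
    row <- sprintf("%.1f%%", 100 * unlist(vals[c("mAP", "mAP50", "mAP75",
                                                 "AR100", "AR300")]))
    writeLines(c(paste(hdr, collapse = "\t"), paste(row, collapse = "\t")),
               tablePath)
  }
  invisible(summary)
}
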