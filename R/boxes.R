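#' Box geometry, overlap measures and class-agnostic NMS
#'
#' Axis-aligned boxes are represented as numeric matrices with one row per
#' box and columns \code{xmin, ymin, xmax, ymax} in continuous pixel
#' coordinates (origin top-left, no +1 in areas, matching the COCO area
#' convention). Scored boxes carry an extra \code{score} column in [0,1].
#'
#' @name boxes-geometry
NULL

#' Construct a box matrix
#'
#' @param xmin,ymin,xmax,ymax numeric vectors of equal length.
#' @return A numeric matrix with columns \code{xmin,ymin,xmax,ymax}.
#' @examples
#' leafBoxes(0, 0, 2, 2)
#' @export
leafBoxes <- function(xmin, ymin, xmax, ymax) {
  m <- cbind(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
             xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  if (any(m[, "xmax"] < m[, "xmin"] | m[, "ymax"] < m[, "ymin"]))
    stop("invalid box: max coordinate smaller than min coordinate")
  m
}

.as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  b <- as.matrix(b)
  if (ncol(b) < 4) stop("boxes need 4 coordinate columns")
  b
}

#' Box areas
#' @param boxes box matrix.
#' @return numeric vector of areas, \code{(xmax-xmin)*(ymax-ymin)}.
#' @export
boxArea <- function(boxes) {
  b <- .as_box_matrix(boxes)
  (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
}

#' Pairwise intersection-over-union
#'
#' Computes the full IoU matrix between two box sets. A pair with zero union
#' area has IoU 0 by convention.
#'
#' @param a,b box matrices (n x 4 and m x 4).
#' @return n x m matrix of IoU values in [0,1].
#' @examples
#' boxIoU(leafBoxes(0, 0, 2, 2), leafBoxes(1, 1, 3, 3))  # 1/7
#' @export
boxIoU <- function(a, b) {
  a <- .as_box_matrix(a); b <- .as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  ix1 <- pmax(matrix(a[, 1], n, m), matrix(b[, 1], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(a[, 2], n, m), matrix(b[, 2], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(a[, 3], n, m), matrix(b[, 3], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(a[, 4], n, m), matrix(b[, 4], n, m, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  uni <- outer(boxArea(a), boxArea(b), "+") - inter
  iou <- ifelse(uni > 0, inter / uni, 0)
  matrix(iou, n, m)
}

#' Pairwise generalized IoU
#'
#' GIoU = IoU - (enclosure - union) / enclosure, where the enclosure is the
#' smallest axis-aligned box containing both. Values lie in (-1, 1]; equal
#' boxes give 1, far-apart boxes approach -1.
#'
#' @inheritParams boxIoU
#' @return n x m matrix of GIoU values.
#' @export
boxGIoU <- function(a, b) {
  a <- .as_box_matrix(a); b <- .as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  ix1 <- pmax(matrix(a[, 1], n, m), matrix(b[, 1], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(a[, 2], n, m), matrix(b[, 2], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(a[, 3], n, m), matrix(b[, 3], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(a[, 4], n, m), matrix(b[, 4], n, m, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  uni <- outer(boxArea(a), boxArea(b), "+") - inter
  ex1 <- pmin(matrix(a[, 1], n, m), matrix(b[, 1], n, m, byrow = TRUE))
  ey1 <- pmin(matrix(a[, 2], n, m), matrix(b[, 2], n, m, byrow = TRUE))
  ex2 <- pmax(matrix(a[, 3], n, m), matrix(b[, 3], n, m, byrow = TRUE))
  ey2 <- pmax(matrix(a[, 4], n, m), matrix(b[, 4], n, m, byrow = TRUE))
  enc <- (ex2 - ex1) * (ey2 - ey1)
  iou <- ifelse(uni > 0, inter / uni, 0)
  g <- iou - ifelse(enc > 0, (enc - uni) / enc, 0)
  matrix(g, n, m)
}

#' Class-agnostic non-maximum suppression
#'
#' Greedy descending-score suppression ignoring any class labels, as used
#' for culling crowded near-duplicate queries. Ties on equal scores are
#' broken by the lower original index so the result is deterministic.
#'
#' @param boxes box matrix (n x 4).
#' @param scores numeric vector of length n, values in [0,1].
#' @param iouThreshold suppress a box when its IoU with an already-kept box
#'   exceeds this value; in (0, 1]. Default 0.7, a common crowded-scene
#'   setting.
#' @return Integer vector of kept row indices, in descending score order.
#' @examples
#' b <- leafBoxes(c(0, 0), c(0, 0), c(2, 2), c(2, 2))
#' classAgnosticNMS(b, c(0.9, 0.8), 0.7)  # keeps only the first
#' @export
classAgnosticNMS <- function(boxes, scores, iouThreshold = 0.7) {
  if (length(scores) == 0) return(integer(0))
  stopifnot(iouThreshold > 0, iouThreshold <= 1,
            all(scores >= 0), all(scores <= 1))
  b <- .as_box_matrix(boxes)
  stopifnot(nrow(b) == length(scores))
  ord <- order(-scores, seq_along(scores))
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0) {
      keep <- i
    } else {
      ious <- boxIoU(b[i, , drop = FALSE], b[keep, , drop = FALSE])
      if (all(ious <= iouThreshold)) keep <- c(keep, i)
    }
  }
  keep
}

#' Convert normalized center-form boxes to corner form
#'
#' Decoder queries carry boxes as normalized \code{(cx, cy, w, h)} in [0,1];
#' geometry and COCO I/O use absolute corner form. The conversion is exact
#' and invertible.
#'
#' @param cboxes matrix with columns \code{cx, cy, w, h}, all in [0,1].
#' @param width,height image size in pixels.
#' @return box matrix in absolute corner form.
#' @export
centerToCorner <- function(cboxes, width, height) {
  c_ <- .as_box_matrix(cboxes)
  if (any(c_[, 3] < 0) || any(c_[, 4] < 0)) stop("negative width or height")
  leafBoxes((c_[, 1] - c_[, 3] / 2) * width,
            (c_[, 2] - c_[, 4] / 2) * height,
            (c_[, 1] + c_[, 3] / 2) * width,
            (c_[, 2] + c_[, 4] / 2) * height)
}

#' Convert corner-form boxes to normalized center form
#' @param boxes box matrix in absolute corner form.
#' @inheritParams centerToCorner
#' @return matrix with columns \code{cx, cy, w, h} normalized by image size.
#' @export
cornerToCenter <- function(boxes, width, height) {
  b <- .as_box_matrix(boxes)
  cbind(cx = (b[, 1] + b[, 3]) / 2 / width,
        cy = (b[, 2] + b[, 4]) / 2 / height,
        w = (b[, 3] - b[, 1]) / width,
        h = (b[, 4] - b[, 2]) / height)
}

#' Corner-form / COCO xywh conversions
#'
#' COCO annotations store \code{[x, y, width, height]}; these helpers map to
#' and from the package's corner form.
#'
#' @param xywh matrix with columns x, y, width, height.
#' @return box matrix in corner form (\code{cocoToCorner}) or xywh matrix
#'   (\code{cornerToCoco}).
#' @export
cocoToCorner <- function(xywh) {
  m <- .as_box_matrix(xywh)
  leafBoxes(m[, 1], m[, 2], m[, 1] + m[, 3], m[, 2] + m[, 4])
}

#' @rdname cocoToCorner
#' @param boxes box matrix in corner form.
#' @export
cornerToCoco <- function(boxes) {
  b <- .as_box_matrix(boxes)
  cbind(x = b[, 1], y = b[, 2], width = b[, 3] - b[, 1], height = b[, 4] - b[, 2])
}
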