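#' Sliding-window tiling specification
#'
#' Defaults follow the dataset-construction protocol for high-resolution
#' canopy mosaics: a 9504 x 6336 pixel window advanced with a 5000 pixel
#' step, with a final window clamped to the image edge so every source
#' pixel is covered.
#'
#' @slot windowWidth,windowHeight window size in pixels.
#' @slot step step size in pixels (shared by both axes).
#' @slot clamp add a final edge-clamped window when the regular grid falls
#'   short of the image extent.
#' @exportClass TileSpec
setClass("TileSpec",
         representation(windowWidth = "numeric", windowHeight = "numeric",
                        step = "numeric", clamp = "logical"),
         validity = function(object) {
           if (object@step <= 0) return("step must be positive")
           if (object@windowWidth <= 0 || object@windowHeight <= 0)
             return("window dimensions must be positive")
           TRUE
         })

#' Construct a TileSpec
#' @param windowWidth,windowHeight window size in pixels.
#' @param step step size in pixels.
#' @param clamp clamp the final window to the image edge.
#' @return A \code{\linkS4class{TileSpec}}.
#' @export
tileSpec <- function(windowWidth = 9504, windowHeight = 6336, step = 5000,
                     clamp = TRUE) {
  new("TileSpec", windowWidth = as.numeric(windowWidth),
      windowHeight = as.numeric(windowHeight), step = as.numeric(step),
      clamp = clamp)
}

setMethod("show", "TileSpec", function(object) {
  cat(sprintf("TileSpec window %gx%g, step %g, clamp=%s\n",
              object@windowWidth, object@windowHeight, object@step,
              object@clamp))
})

.axis_origins <- function(src, win, step, clamp) {
  if (win >= src) return(0)
  o <- seq(0, src - win, by = step)
  if (clamp && max(o) + win < src) o <- c(o, src - win)
  o
}

#' Sliding-window origins over a source image
#'
#' Origins advance at 0, step, 2*step, ... independently per axis while the
#' window fits; if coverage falls short of the image extent a final origin
#' clamped to \code{source - window} is added. When the window exceeds the
#' source in a dimension, a single origin at 0 is returned with attribute
#' \code{"cropped" = TRUE} (the window must be cropped to the source).
#' Origins are returned row-major.
#'
#' @param sourceWidth,sourceHeight source image size in pixels.
#' @param spec a \code{\linkS4class{TileSpec}}.
#' @return matrix with columns \code{x}, \code{y} of window origins.
#' @examples
#' slidingWindows(14504, 6336, tileSpec())  # x origins 0 and 5000
#' @export
slidingWindows <- function(sourceWidth, sourceHeight, spec = tileSpec()) {
  stopifnot(sourceWidth > 0, sourceHeight > 0)
  xs <- .axis_origins(sourceWidth, spec@windowWidth, spec@step, spec@clamp)
  ys <- .axis_origins(sourceHeight, spec@windowHeight, spec@step, spec@clamp)
  out <- cbind(x = rep(xs, times = length(ys)),
               y = rep(ys, each = length(xs)))
  attr(out, "cropped") <- spec@windowWidth > sourceWidth ||
    spec@windowHeight > sourceHeight
  out
}

#' Clip and translate boxes into a tile window
#'
#' Boxes intersecting the window are clipped to it and translated to window
#' coordinates. A box is kept only when at least a third of its original
#' area survives the clipping, reusing the 1/3 visibility convention of the
#' annotation protocol for crop-boundary boxes.
#'
#' @param boxes box matrix (corner form, source coordinates).
#' @param window numeric \code{c(x, y, width, height)} of the tile.
#' @param minAreaFraction minimum surviving area fraction (default 1/3).
#' @return box matrix in window coordinates; kept source row indices as
#'   attribute \code{"kept"}.
#' @export
cropBoxes <- function(boxes, window, minAreaFraction = 1 / 3) {
  b <- .as_box_matrix(boxes)
  if (length(window) != 4) stop("window must be c(x, y, width, height)")
  wx0 <- window[1]; wy0 <- window[2]
  wx1 <- wx0 + window[3]; wy1 <- wy0 + window[4]
  cx0 <- pmax(b[, 1], wx0); cy0 <- pmax(b[, 2], wy0)
  cx1 <- pmin(b[, 3], wx1); cy1 <- pmin(b[, 4], wy1)
  clipped <- pmax(cx1 - cx0, 0) * pmax(cy1 - cy0, 0)
  orig <- boxArea(b)
  keep <- which(orig > 0 & clipped >= minAreaFraction * orig)
  out <- leafBoxes(cx0[keep] - wx0, cy0[keep] - wy0,
                   cx1[keep] - wx0, cy1[keep] - wy0)
  attr(out, "kept") <- keep
  out
}

#' Count-based tile/image screening
#'
#' Keep a tile (or image) iff it holds at least \code{minBoxes} annotated
#' leaves. The tiling protocol removes windows with fewer than 50 blades;
#' the full-image screening analog uses a minimum of 200 visible leaves.
#'
#' @param count nonnegative annotation count.
#' @param minBoxes threshold (50 for tiles, 200 for full images).
#' @return logical: keep (TRUE) or reject (FALSE).
#' @export
screenTile <- function(count, minBoxes = 50) {
  stopifnot(count >= 0)
  count >= minBoxes
}

#' Dataset density statistics
#'
#' Boxes-per-image density, truncated (not rounded) to two decimals: the
#' convention under which 85375 boxes over 1696 images prints as 50.33.
#'
#' @param imageCount number of images (> 0).
#' @param boxCount number of annotation boxes.
#' @return list with \code{images}, \code{boxes} and \code{density}.
#' @examples
#' densityStats(1696, 85375)$density  # 50.33
#' @export
densityStats <- function(imageCount, boxCount) {
  if (imageCount <= 0) stop("image count must be positive")
  density <- floor(boxCount / imageCount * 100) / 100
  list(images = imageCount, boxes = boxCount, density = density)
}

#' Tile a COCO dataset with sliding windows
#'
#' Applies \code{\link{slidingWindows}} to every source image, clips the
#' annotations into each window with \code{\link{cropBoxes}}, screens tiles
#' with \code{\link{screenTile}}, and returns the surviving tiles as a new
#' in-memory COCO-style structure.
#'
#' @param coco list from \code{\link{readCocoDataset}}.
#' @param spec a \code{\linkS4class{TileSpec}}.
#' @param minBoxes minimum boxes for a tile to survive screening.
#' @return list with \code{images}, \code{annotations} data.frames (tile
#'   windows become images) and \code{tiles}, the per-tile bookkeeping
#'   (source image, origin, kept counts).
#' @export
tileDataset <- function(coco, spec = tileSpec(), minBoxes = 50) {
  images <- list(); annotations <- list(); tiles <- list()
  tid <- 0L; aid <- 0L
  for (r in seq_len(nrow(coco$images))) {
    im <- coco$images[r, ]
    ann <- coco$annotations[coco$annotations$image_id == im$id, , drop = FALSE]
    boxes <- if (nrow(ann) > 0)
      cocoToCorner(cbind(ann$x, ann$y, ann$width, ann$height))
    else leafBoxes(numeric(0), numeric(0), numeric(0), numeric(0))
    origins <- slidingWindows(im$width, im$height, spec)
    ww <- min(spec@windowWidth, im$width)
    wh <- min(spec@windowHeight, im$height)
    for (k in seq_len(nrow(origins))) {
      win <- c(origins[k, "x"], origins[k, "y"], ww, wh)
      cropped <- if (nrow(boxes) > 0) cropBoxes(boxes, win)
      else leafBoxes(numeric(0), numeric(0), numeric(0), numeric(0))
      if (!screenTile(nrow(cropped), minBoxes)) next
      tid <- tid + 1L
      images[[tid]] <- data.frame(id = tid,
                                  file_name = sprintf("%s_tile%03d.png",
                                                      sub("\\.[^.]+$", "", im$file_name), k),
                                  width = ww, height = wh)
      tiles[[tid]] <- data.frame(tile_id = tid, source_image_id = im$id,
                                 x = win[1], y = win[2], boxes = nrow(cropped))
      if (nrow(cropped) > 0) {
        xywh <- cornerToCoco(cropped)
        for (j in seq_len(nrow(xywh))) {
          aid <- aid + 1L
          annotations[[aid]] <- data.frame(
            id = aid, image_id = tid, category_id = 1L,
            x = xywh[j, 1], y = xywh[j, 2],
            width = xywh[j, 3], height = xywh[j, 4],
            area = xywh[j, 3] * xywh[j, 4])
        }
      }
    }
  }
  list(images = if (tid > 0) do.call(rbind, images) else
         data.frame(id = integer(0), file_name = character(0),
                    width = numeric(0), height = numeric(0)),
       annotations = if (aid > 0) do.call(rbind, annotations) else
         data.frame(id = integer(0), image_id = integer(0),
                    category_id = integer(0), x = numeric(0), y = numeric(0),
                    width = numeric(0), height = numeric(0), area = numeric(0)),
       tiles = if (tid > 0) do.call(rbind, tiles) else
         data.frame(tile_id = integer(0), source_image_id = integer(0),
                    x = numeric(0), y = numeric(0), boxes = integer(0)))
}
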