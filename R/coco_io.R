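#' COCO detection JSON input/output
#'
#' Readers and writers for the COCO object-detection annotation format
#' (\code{images}, \code{annotations} with \code{[x, y, width, height]}
#' boxes, \code{categories}), the interchange format of the dataset
#' pipeline, the scene generator and the evaluator. A single foreground
#' category ("leaf") is used throughout.
#'
#' @name coco-io
NULL

#' Write annotated scenes as a COCO dataset
#'
#' Writes one PNG per scene plus an \code{annotations.json} with COCO
#' detection annotations of the visible leaf parts (xywh boxes, pixel
#' areas, \code{iscrowd = 0}, one "leaf" category). A round-trip read
#' reproduces the boxes exactly.
#'
#' @param scenes list of \code{\linkS4class{LeafScene}} objects.
#' @param outDir output directory (created if missing).
#' @param writeImages write the PNG files (TRUE) or only the JSON.
#' @return path of the written JSON, invisibly.
#' @export
writeCocoDataset <- function(scenes, outDir, writeImages = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  images <- list()
  annotations <- list()
  ann_id <- 1L
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    fn <- sprintf("scene_%04d.png", i)
    if (writeImages)
      png::writePNG(sceneImage(sc), file.path(outDir, fn))
    images[[i]] <- list(id = i, file_name = fn,
                        width = sc@spec@width, height = sc@spec@height)
    boxes <- annotateScene(sc)
    if (nrow(boxes) > 0) {
      xywh <- cornerToCoco(boxes)
      for (j in seq_len(nrow(xywh))) {
        annotations[[ann_id]] <- list(
          id = ann_id, image_id = i, category_id = 1L,
          bbox = as.numeric(xywh[j, ]),
          area = as.numeric(xywh[j, "width"] * xywh[j, "height"]),
          iscrowd = 0L)
        ann_id <- ann_id + 1L
      }
    }
  }
  path <- file.path(outDir, "annotations.json")
  jsonlite::write_json(
    list(images = images, annotations = annotations,
         categories = list(list(id = 1L, name = "leaf"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO detection JSON
#'
#' @param path path to the JSON file.
#' @return list with data.frames \code{images} (id, file_name, width,
#'   height), \code{annotations} (id, image_id, category_id, x, y, width,
#'   height, area) and \code{categories}.
#' @export
readCocoDataset <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  images <- do.call(rbind, lapply(j$images, function(im)
    data.frame(id = im$id, file_name = im$file_name,
               width = im$width, height = im$height)))
  if (is.null(images))
    images <- data.frame(id = integer(0), file_name = character(0),
                         width = integer(0), height = integer(0))
  annotations <- do.call(rbind, lapply(j$annotations, function(a)
    data.frame(id = a$id, image_id = a$image_id,
               category_id = a$category_id,
               x = a$bbox[[1]], y = a$bbox[[2]],
               width = a$bbox[[3]], height = a$bbox[[4]],
               area = a$area)))
  if (is.null(annotations))
    annotations <- data.frame(id = integer(0), image_id = integer(0),
                              category_id = integer(0), x = numeric(0),
                              y = numeric(0), width = numeric(0),
                              height = numeric(0), area = numeric(0))
  categories <- do.call(rbind, lapply(j$categories, function(ct)
    data.frame(id = ct$id, name = ct$name)))
  list(images = images, annotations = annotations, categories = categories)
}

#' Group COCO annotations by image for evaluation
#'
#' @param coco a list as returned by \code{\link{readCocoDataset}}.
#' @return named list (by image id, as character) of lists with corner-form
#'   \code{boxes}, the ground-truth layout expected by
#'   \code{\link{evaluateDetections}}.
#' @export
cocoGroundTruths <- function(coco) {
  out <- list()
  for (id in coco$images$id) {
    ann <- coco$annotations[coco$annotations$image_id == id, , drop = FALSE]
    boxes <- if (nrow(ann) > 0)
      cocoToCorner(cbind(ann$x, ann$y, ann$width, ann$height))
    else leafBoxes(numeric(0), numeric(0), numeric(0), numeric(0))
    out[[as.character(id)]] <- list(boxes = boxes)
  }
  out
}
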