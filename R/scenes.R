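#' Specification of a synthetic dense-leaf scene
#'
#' Parameters of the seeded generator that emulates a densely occluded leaf
#' canopy: leaves are textured ellipses with a midrib and a two-sided
#' illumination gradient, painted back-to-front so that later leaves occlude
#' earlier ones, with per-leaf visibility computed by exact pixel counting.
#'
#' @slot width,height image size in pixels.
#' @slot lambda mean instance count per scene (Poisson); the emulated
#'   canopies average about 50 leaves per image.
#' @slot axisA,axisB ranges (pixels) of the ellipse semi-major and
#'   semi-minor axes.
#' @slot angleRange orientation range in radians.
#' @slot illumAmplitude amplitude of the two-sided (across-midrib)
#'   illumination difference, as a fraction of base brightness.
#' @slot veinContrast darkening applied along the midrib line.
#' @slot minVisibleFraction leaves whose visible fraction falls below this
#'   are left unannotated (default 1/3).
#' @slot seed RNG seed; identical specs regenerate bit-identical scenes.
#' @exportClass SceneSpec
setClass("SceneSpec",
         representation(width = "integer", height = "integer",
                        lambda = "numeric", axisA = "numeric",
                        axisB = "numeric", angleRange = "numeric",
                        illumAmplitude = "numeric", veinContrast = "numeric",
                        minVisibleFraction = "numeric", seed = "integer"),
         validity = function(object) {
           if (object@lambda < 0) return("lambda must be >= 0")
           if (object@minVisibleFraction <= 0 || object@minVisibleFraction > 1)
             return("minVisibleFraction must lie in (0, 1]")
           if (object@width < 1 || object@height < 1)
             return("image must be at least 1x1")
           TRUE
         })

#' Construct a SceneSpec
#'
#' Defaults emulate the target canopy statistics: about 50 mutually
#' occluding leaves per 256x256 scene with heavy pairwise overlap, visible
#' parts annotated only when at least a third of the leaf shows.
#'
#' @param width,height image size in pixels.
#' @param lambda mean leaf count (Poisson).
#' @param axisA,axisB semi-axis ranges \code{c(min, max)} in pixels.
#' @param angleRange orientation range in radians.
#' @param illumAmplitude two-sided illumination amplitude.
#' @param veinContrast midrib darkening.
#' @param minVisibleFraction annotation visibility threshold.
#' @param seed RNG seed.
#' @return A \code{\linkS4class{SceneSpec}}.
#' @export
sceneSpec <- function(width = 256, height = 256, lambda = 50,
                      axisA = c(18, 34), axisB = c(10, 22),
                      angleRange = c(0, pi), illumAmplitude = 0.25,
                      veinContrast = 0.15, minVisibleFraction = 1 / 3,
                      seed = 1L) {
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      lambda = as.numeric(lambda), axisA = as.numeric(axisA),
      axisB = as.numeric(axisB), angleRange = as.numeric(angleRange),
      illumAmplitude = as.numeric(illumAmplitude),
      veinContrast = as.numeric(veinContrast),
      minVisibleFraction = as.numeric(minVisibleFraction),
      seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec %dx%d, lambda=%.1f, seed=%d, minVisible=%.3f\n",
              object@width, object@height, object@lambda, object@seed,
              object@minVisibleFraction))
})

#' A rendered synthetic leaf scene
#'
#' @slot image \code{(H, W, 3)} array of RGB values in [0, 1].
#' @slot owner integer \code{(H, W)} matrix: 0 for background, otherwise
#'   the id of the front-most (visible) leaf at that pixel.
#' @slot instances data.frame with one row per leaf: ellipse geometry,
#'   paint (depth) order, full and visible mask areas and visible fraction.
#' @slot spec the generating \code{\linkS4class{SceneSpec}}.
#' @exportClass LeafScene
setClass("LeafScene",
         representation(image = "array", owner = "matrix",
                        instances = "data.frame", spec = "SceneSpec"))

setMethod("show", "LeafScene", function(object) {
  cat(sprintf("LeafScene %dx%d with %d leaf instance(s); %d visible >= %.0f%%\n",
              ncol(object@owner), nrow(object@owner), nrow(object@instances),
              sum(object@instances$visibleFraction >=
                    object@spec@minVisibleFraction),
              100 * object@spec@minVisibleFraction))
})

#' @describeIn sampleScene RGB image array of a scene.
#' @export
setGeneric("sceneImage", function(object) standardGeneric("sceneImage"))

#' @rdname sampleScene
#' @export
setMethod("sceneImage", "LeafScene", function(object) object@image)

#' @describeIn sampleScene per-leaf instance table of a scene.
#' @export
setGeneric("sceneInstances", function(object) standardGeneric("sceneInstances"))

#' @rdname sampleScene
#' @export
setMethod("sceneInstances", "LeafScene", function(object) object@instances)

#' @describeIn sampleScene visibility (owner) matrix of a scene.
#' @export
setGeneric("sceneOwner", function(object) standardGeneric("sceneOwner"))

#' @rdname sampleScene
#' @export
setMethod("sceneOwner", "LeafScene", function(object) object@owner)

#' Render a synthetic dense-leaf scene
#'
#' Draws the instance count from Poisson(lambda), places elliptical leaves
#' uniformly, and paints them back-to-front (painter's algorithm) so that
#' later leaves occlude earlier ones. Each leaf carries a slightly jittered
#' green base colour, a darker midrib line, a fine cross-vein texture and a
#' two-sided illumination gradient (one half of the blade brighter than the
#' other). Visible areas are exact pixel counts from the ownership matrix.
#' Deterministic for a fixed spec (including its seed).
#'
#' @param spec a \code{\linkS4class{SceneSpec}}.
#' @return A \code{\linkS4class{LeafScene}}.
#' @export
sampleScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  set.seed(spec@seed)
  W <- spec@width; H <- spec@height
  n <- stats::rpois(1, spec@lambda)

  # soil-toned background with a mild diagonal illumination ramp
  img <- array(0, dim = c(H, W, 3))
  ramp <- outer(seq(0, 1, length.out = H), seq(0, 1, length.out = W)) * 0.08
  img[, , 1] <- 0.18 + ramp
  img[, , 2] <- 0.14 + ramp
  img[, , 3] <- 0.10 + ramp
  owner <- matrix(0L, H, W)

  inst <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                     a = numeric(0), b = numeric(0), angle = numeric(0),
                     depth = integer(0), fullArea = numeric(0))
  if (n > 0) {
    cx <- stats::runif(n, 0, W)
    cy <- stats::runif(n, 0, H)
    a <- stats::runif(n, spec@axisA[1], spec@axisA[2])
    b <- stats::runif(n, spec@axisB[1], spec@axisB[2])
    ang <- stats::runif(n, spec@angleRange[1], spec@angleRange[2])
    gjit <- stats::runif(n, -0.08, 0.08)
    bright_side <- sample(c(-1, 1), n, replace = TRUE)
    full <- numeric(n)

    for (i in seq_len(n)) {
      x0 <- max(1L, floor(cx[i] - a[i])); x1 <- min(W, ceiling(cx[i] + a[i]))
      y0 <- max(1L, floor(cy[i] - a[i])); y1 <- min(H, ceiling(cy[i] + a[i]))
      if (x0 > x1 || y0 > y1) next
      cols <- x0:x1; rows <- y0:y1
      dxm <- matrix(cols - 0.5 - cx[i], length(rows), length(cols), byrow = TRUE)
      dym <- matrix(rows - 0.5 - cy[i], length(rows), length(cols))
      u <- dxm * cos(ang[i]) + dym * sin(ang[i])
      v <- -dxm * sin(ang[i]) + dym * cos(ang[i])
      mask <- (u / a[i])^2 + (v / b[i])^2 <= 1
      full[i] <- sum(mask)
      if (full[i] == 0) next
      idx <- which(mask, arr.ind = TRUE)
      ri <- rows[idx[, 1]]; ci <- cols[idx[, 2]]
      owner[cbind(ri, ci)] <- i
      # colour: base green + jitter, two-sided illumination across the
      # midrib, darker midrib line, faint cross-vein striping
      vv <- v[idx]; uu <- u[idx]
      shade <- 1 + spec@illumAmplitude * bright_side[i] * tanh(3 * vv / b[i])
      vein <- ifelse(abs(vv) < 0.05 * b[i], 1 - spec@veinContrast, 1)
      stripe <- 1 + 0.05 * sin(uu * 1.5)
      g <- pmin(pmax((0.55 + gjit[i]) * shade * vein * stripe, 0), 1)
      r <- pmin(pmax((0.22 + 0.5 * gjit[i]) * shade * vein, 0), 1)
      bl <- pmin(pmax(0.16 * shade, 0), 1)
      img[cbind(ri, ci, 1L)] <- r
      img[cbind(ri, ci, 2L)] <- g
      img[cbind(ri, ci, 3L)] <- bl
    }
    visible <- tabulate(owner[owner > 0L], nbins = n)
    inst <- data.frame(id = seq_len(n), cx = cx, cy = cy, a = a, b = b,
                       angle = ang, depth = seq_len(n), fullArea = full)
    inst$visibleArea <- visible
    inst$visibleFraction <- ifelse(full > 0, visible / full, 0)
  } else {
    inst$visibleArea <- numeric(0)
    inst$visibleFraction <- numeric(0)
  }
  new("LeafScene", image = img, owner = owner, instances = inst, spec = spec)
}

#' Annotate the visible parts of a scene
#'
#' One ground-truth box per leaf whose visible fraction reaches
#' \code{minVisibleFraction}; the box tightly bounds the visible pixel set
#' only (not the occluded, amodal extent). Leaves below the threshold are
#' omitted, mirroring the rule that blades less than a third visible are
#' not marked.
#'
#' @param scene a \code{\linkS4class{LeafScene}}.
#' @param minVisibleFraction visibility threshold; defaults to the scene
#'   spec's value.
#' @return box matrix (corner form) with a row per annotated leaf and the
#'   leaf ids as attribute \code{"leafIds"}.
#' @export
annotateScene <- function(scene, minVisibleFraction = NULL) {
  stopifnot(is(scene, "LeafScene"))
  if (is.null(minVisibleFraction))
    minVisibleFraction <- scene@spec@minVisibleFraction
  inst <- scene@instances
  keep <- which(inst$visibleFraction >= minVisibleFraction &
                  inst$visibleArea > 0)
  if (length(keep) == 0) {
    out <- leafBoxes(numeric(0), numeric(0), numeric(0), numeric(0))
    attr(out, "leafIds") <- integer(0)
    return(out)
  }
  vis <- which(scene@owner > 0L, arr.ind = TRUE)
  ids <- scene@owner[vis]
  xmin <- tapply(vis[, 2], ids, min) - 1
  xmax <- tapply(vis[, 2], ids, max)
  ymin <- tapply(vis[, 1], ids, min) - 1
  ymax <- tapply(vis[, 1], ids, max)
  present <- as.integer(names(xmin))
  sel <- match(keep, present)
  out <- leafBoxes(xmin[sel], ymin[sel], xmax[sel], ymax[sel])
  attr(out, "leafIds") <- inst$id[keep]
  out
}
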