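# Seeded fixture builders shared across tests.

random_boxes <- function(n, extent = 10, max_side = 4) {
  x <- stats::runif(n, 0, extent - max_side)
  y <- stats::runif(n, 0, extent - max_side)
  w <- stats::runif(n, 0.5, max_side)
  h <- stats::runif(n, 0.5, max_side)
  leafBoxes(x, y, x + w, y + h)
}

small_scene <- function(seed, lambda = 10, size = 64) {
  sampleScene(sceneSpec(width = size, height = size, lambda = lambda,
                        axisA = c(8, 14), axisB = c(5, 9), seed = seed))
}

smoke_scenes <- function(n = 20, seed0 = 100) {
  lapply(seq_len(n), function(i) small_scene(seed0 + i))
}

small_model <- function(seed = 2, ...) {
  buildModel(modelConfig(channels = 16, nOri = 30, nExtra = 30, ...),
             seed = seed)
}

# Jittered pseudo-detections for a scene: noisy copies of the ground truth
# plus spurious boxes, with seeded scores.
pseudo_detections <- function(gt, seed, width, height, spurious = 5) {
  set.seed(seed)
  n <- nrow(gt)
  jit <- gt + matrix(stats::rnorm(4 * n, sd = 1.5), n, 4)
  jit[, 1] <- pmin(jit[, 1], jit[, 3] - 0.5)
  jit[, 2] <- pmin(jit[, 2], jit[, 4] - 0.5)
  sp <- random_boxes(spurious, extent = width, max_side = 12)
  boxes <- rbind(jit[, 1:4, drop = FALSE], sp[, 1:4, drop = FALSE])
  list(boxes = boxes,
       scores = c(stats::runif(n, 0.5, 1), stats::runif(spurious, 0, 0.6)))
}
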