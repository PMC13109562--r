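# Independent straight-line oracles. These deliberately avoid the package's
# code paths (no autodiff, no im2col, no clue): loops and direct formulas
# only, so agreement with the package is a genuine cross-check.

## ---- suppression ----------------------------------------------------------

# Greedy suppression by repeated argmax with explicit suppression marks.
oracle_nms <- function(boxes, scores, thr) {
  n <- length(scores)
  state <- rep("open", n)
  kept <- integer(0)
  repeat {
    open <- which(state == "open")
    if (length(open) == 0) break
    best <- open[order(-scores[open], open)][1]
    kept <- c(kept, best)
    state[best] <- "kept"
    for (j in which(state == "open")) {
      if (oracle_iou(boxes[best, ], boxes[j, ]) > thr) state[j] <- "suppressed"
    }
  }
  kept
}

oracle_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) inter <- 0 else inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

## ---- assignment -----------------------------------------------------------

# All permutations of v (small n only).
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Minimum total cost over all complete one-to-one assignments of the
# smaller side, by exhaustive enumeration.
oracle_assignment_min <- function(cost) {
  P <- nrow(cost); G <- ncol(cost)
  if (P == 0 || G == 0) return(0)
  best <- Inf
  if (P <= G) {
    for (perm in oracle_perms(seq_len(G))) {
      tot <- sum(cost[cbind(seq_len(P), perm[seq_len(P)])])
      best <- min(best, tot)
    }
  } else {
    for (perm in oracle_perms(seq_len(P))) {
      tot <- sum(cost[cbind(perm[seq_len(G)], seq_len(G))])
      best <- min(best, tot)
    }
  }
  best
}

# k explicit sequential one-to-one rounds over a shrinking prediction pool,
# each round solved by the package's one-to-one matcher (the sequential
# structure, not the solver, is what this cross-checks).
oracle_topk_rounds <- function(cost, k) {
  pool <- seq_len(nrow(cost))
  pairs <- NULL
  for (r in seq_len(k)) {
    if (length(pool) == 0) break
    a <- hungarianMatch(cost[pool, , drop = FALSE])
    ap <- assignmentPairs(a)
    if (nrow(ap) == 0) break
    pairs <- rbind(pairs, cbind(pred = pool[ap[, "pred"]], gt = ap[, "gt"]))
    pool <- setdiff(pool, pool[ap[, "pred"]])
  }
  if (!is.null(pairs)) {
    rownames(pairs) <- NULL
    storage.mode(pairs) <- "integer"
  }
  pairs
}

## ---- pyramid fusion (plain-array recomputation of the fusion equations) ---

oracle_conv1x1 <- function(x, w, b) {
  d <- dim(x); co <- dim(w)[1]
  out <- array(0, dim = c(co, d[2], d[3]))
  for (o in seq_len(co)) {
    acc <- array(0, dim = d[2:3])
    for (ci in seq_len(d[1])) acc <- acc + w[o, ci, 1, 1] * x[ci, , ]
    out[o, , ] <- acc + b[o]
  }
  out
}

oracle_conv3x3 <- function(x, w, b) {
  d <- dim(x); co <- dim(w)[1]
  H <- d[2]; W <- d[3]
  xp <- array(0, dim = c(d[1], H + 2, W + 2))
  xp[, 2:(H + 1), 2:(W + 1)] <- x
  out <- array(0, dim = c(co, H, W))
  for (o in seq_len(co)) {
    acc <- matrix(0, H, W)
    for (ci in seq_len(d[1])) {
      for (di in 1:3) {
        for (dj in 1:3) {
          acc <- acc + w[o, ci, di, dj] * xp[ci, di:(di + H - 1), dj:(dj + W - 1)]
        }
      }
    }
    out[o, , ] <- acc + b[o]
  }
  out
}

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

oracle_top_transform <- function(x, tp) {
  oracle_conv1x1(oracle_conv3x3(oracle_conv1x1(x, tp$mlp1_w, tp$mlp1_b),
                                tp$conv_w, tp$conv_b),
                 tp$mlp2_w, tp$mlp2_b)
}

oracle_spatial_gate <- function(p1, p2, ap) {
  oracle_sigmoid(oracle_conv1x1(p1, ap$sp1_w, ap$sp1_b) +
                   oracle_conv1x1(p2, ap$sp2_w, ap$sp2_b))
}

oracle_channel_gate <- function(p1, p2, ap) {
  d <- dim(p1)
  p12 <- array(0, dim = c(2 * d[1], d[2], d[3]))
  p12[seq_len(d[1]), , ] <- p1
  p12[d[1] + seq_len(d[1]), , ] <- p2
  pooled <- apply(p12, 1, mean)
  pc <- oracle_sigmoid(as.numeric(ap$ch_w %*% pooled) + ap$ch_b)
  gated <- p12
  for (cc in seq_len(2 * d[1])) gated[cc, , ] <- p12[cc, , ] * pc[cc]
  list(fc = oracle_conv1x1(gated, ap$red_w, ap$red_b), pc = pc)
}

oracle_afa_fuse <- function(p1, p2, ap) {
  fs <- oracle_spatial_gate(p1, p2, ap)
  fc <- oracle_channel_gate(p1, p2, ap)$fc
  out <- fc
  for (cc in seq_len(dim(fc)[1])) out[cc, , ] <- fc[cc, , ] * fs[1, , ]
  out
}

oracle_upsample_nearest <- function(x, outH, outW) {
  d <- dim(x)
  ih <- pmin(d[2], floor((seq_len(outH) - 1) * d[2] / outH) + 1)
  iw <- pmin(d[3], floor((seq_len(outW) - 1) * d[3] / outW) + 1)
  x[, ih, iw, drop = FALSE]
}

oracle_progressive_fuse <- function(levels, params) {
  n <- length(levels)
  out <- vector("list", n)
  out[[n]] <- oracle_top_transform(levels[[n]], params$top)
  if (n >= 2) {
    for (i in seq(n - 1, 1)) {
      d <- dim(levels[[i]])
      up <- oracle_upsample_nearest(out[[i + 1]], d[2], d[3])
      out[[i]] <- oracle_afa_fuse(levels[[i]], up, params$afa[[i]])
    }
  }
  out
}

## ---- detection metrics ----------------------------------------------------

# Per-image greedy matching in score order; different bookkeeping from the
# package's implementation (explicit while loop over a candidate table).
oracle_match_image <- function(det_boxes, det_scores, gt_boxes, thr, max_dets) {
  ord <- order(-det_scores, seq_along(det_scores))
  if (length(ord) > max_dets) ord <- ord[seq_len(max_dets)]
  G <- NROW(gt_boxes)
  used <- rep(FALSE, G)
  flags <- logical(length(ord))
  for (r in seq_along(ord)) {
    bi <- det_boxes[ord[r], ]
    best_j <- 0; best_v <- -1
    if (G > 0) {
      for (j in seq_len(G)) {
        if (used[j]) next
        v <- oracle_iou(bi, gt_boxes[j, ])
        if (v > best_v) { best_v <- v; best_j <- j }
      }
    }
    if (best_j > 0 && best_v >= thr) { flags[r] <- TRUE; used[best_j] <- TRUE }
  }
  list(flags = flags, scores = det_scores[ord], matched = sum(used))
}

oracle_ap_101 <- function(flags, num_gt) {
  if (num_gt == 0 || length(flags) == 0) return(0)
  tp <- cumsum(flags); fp <- cumsum(!flags)
  prec <- tp / (tp + fp); rec <- tp / num_gt
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    best <- 0
    for (i in seq_along(rec)) if (rec[i] >= r - 1e-12 && prec[i] > best) best <- prec[i]
    total <- total + best
  }
  total / 101
}

oracle_evaluate <- function(dets, gts, score_threshold = 0.5) {
  grid <- seq(0.5, 0.95, by = 0.05)
  ap_at <- function(thr, max_dets) {
    all_scores <- numeric(0); all_flags <- logical(0); num_gt <- 0
    for (id in names(gts)) {
      num_gt <- num_gt + NROW(gts[[id]]$boxes)
      d <- dets[[id]]
      if (is.null(d) || length(d$scores) == 0) next
      m <- oracle_match_image(d$boxes, d$scores, gts[[id]]$boxes, thr, max_dets)
      all_scores <- c(all_scores, m$scores)
      all_flags <- c(all_flags, m$flags)
    }
    if (length(all_scores) == 0) return(if (num_gt > 0) 0 else NA_real_)
    ord <- order(-all_scores)
    oracle_ap_101(all_flags[ord], num_gt)
  }
  rec_at <- function(thr, max_dets) {
    matched <- 0; num_gt <- 0
    for (id in names(gts)) {
      G <- NROW(gts[[id]]$boxes)
      num_gt <- num_gt + G
      d <- dets[[id]]
      if (is.null(d) || length(d$scores) == 0 || G == 0) next
      m <- oracle_match_image(d$boxes, d$scores, gts[[id]]$boxes, thr, max_dets)
      matched <- matched + m$matched
    }
    if (num_gt == 0) NA_real_ else matched / num_gt
  }
  aps <- vapply(grid, ap_at, numeric(1), max_dets = 100)
  tp <- 0; fp <- 0; fn <- 0
  for (id in names(gts)) {
    G <- NROW(gts[[id]]$boxes)
    d <- dets[[id]]
    keep <- if (is.null(d)) integer(0) else which(d$scores >= score_threshold)
    if (length(keep) == 0) { fn <- fn + G; next }
    m <- oracle_match_image(d$boxes[keep, , drop = FALSE], d$scores[keep],
                            gts[[id]]$boxes, 0.5, Inf)
    tp <- tp + sum(m$flags); fp <- fp + sum(!m$flags)
    fn <- fn + (G - m$matched)
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(mAP = mean(aps, na.rm = TRUE), mAP50 = aps[1], mAP75 = aps[6],
    AR100 = mean(vapply(grid, rec_at, numeric(1), max_dets = 100), na.rm = TRUE),
    AR300 = mean(vapply(grid, rec_at, numeric(1), max_dets = 300), na.rm = TRUE),
    precision = prec, recall = rec,
    F1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

## ---- sinusoidal query encoding -------------------------------------------

oracle_box_encoding <- function(cbox, dim) {
  d4 <- dim / 4
  emb <- numeric(dim)
  for (j in 1:4) {
    for (i in seq_len(d4 / 2)) {
      f <- 10000^(2 * (i - 1) / d4)
      emb[(j - 1) * d4 + 2 * i - 1] <- sin(2 * pi * cbox[j] / f)
      emb[(j - 1) * d4 + 2 * i] <- cos(2 * pi * cbox[j] / f)
    }
  }
  emb
}
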