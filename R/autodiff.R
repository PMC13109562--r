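# Minimal tape-based reverse-mode automatic differentiation over R arrays.
#
# Every trainable component of the package (progressive pyramid fusion, the
# miniature encoder/decoder, the detection losses) is expressed in these
# primitives, so analytic gradients are available for optimisation and for
# finite-difference validation. Nodes are environments carrying a value, an
# accumulated gradient, parent pointers and a backward closure; creation
# order doubles as a topological order because every op is built after its
# parents.

.ad_env <- new.env(parent = emptyenv())
.ad_env$id <- 0L

.ad_next_id <- function() {
  .ad_env$id <- .ad_env$id + 1L
  .ad_env$id
}

# backward: function(grad) -> list of gradients, one per parent, each either
# NULL (no flow) or an array conformable with that parent's value.
ad_node <- function(value, parents = list(), backward = NULL, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires <- requires || any(vapply(parents, function(p) p$requires, logical(1)))
  e$id <- .ad_next_id()
  class(e) <- "adNode"
  e
}

ad_param <- function(value) ad_node(value, requires = TRUE)
ad_const <- function(value) ad_node(value)

as_ad <- function(x) if (inherits(x, "adNode")) x else ad_const(x)

ad_value <- function(x) if (inherits(x, "adNode")) x$value else x

.ad_accum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse sweep from a scalar root. Gradients land in $grad of every node
# reachable from root that has requires = TRUE.
ad_backward <- function(root) {
  stopifnot(inherits(root, "adNode"), length(root$value) == 1L)
  nodes <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack) > 0L) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  all_nodes <- as.list(nodes)
  ord <- order(vapply(all_nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  all_nodes <- all_nodes[ord]
  root$grad <- array(1, dim = if (is.null(dim(root$value))) 1L else dim(root$value))
  for (n in all_nodes) {
    if (is.null(n$grad) || is.null(n$backward) || !n$requires) next
    gs <- n$backward(n$grad)
    for (j in seq_along(n$parents)) {
      if (!is.null(gs[[j]])) .ad_accum(n$parents[[j]], gs[[j]])
    }
  }
  invisible(root)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- elementwise ----------------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value * b$value, list(a, b),
          function(g) list(g * b$value, g * a$value))
}

ad_div <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value / b$value, list(a, b),
          function(g) list(g / b$value, -g * a$value / (b$value^2)))
}

ad_scale <- function(a, k) {
  a <- as_ad(a)
  ad_node(a$value * k, list(a), function(g) list(g * k))
}

ad_shift <- function(a, k) {
  a <- as_ad(a)
  ad_node(a$value + k, list(a), function(g) list(g))
}

ad_neg <- function(a) ad_scale(a, -1)

ad_pow <- function(a, p) {
  a <- as_ad(a)
  ad_node(a$value^p, list(a), function(g) list(g * p * a$value^(p - 1)))
}

ad_log <- function(a) {
  a <- as_ad(a)
  ad_node(log(a$value), list(a), function(g) list(g / a$value))
}

ad_exp <- function(a) {
  a <- as_ad(a)
  v <- exp(a$value)
  ad_node(v, list(a), function(g) list(g * v))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_relu <- function(a) {
  a <- as_ad(a)
  m <- a$value > 0
  ad_node(a$value * m, list(a), function(g) list(g * m))
}

ad_tanh <- function(a) {
  a <- as_ad(a)
  v <- tanh(a$value)
  ad_node(v, list(a), function(g) list(g * (1 - v^2)))
}

ad_abs <- function(a) {
  a <- as_ad(a)
  s <- sign(a$value)
  ad_node(abs(a$value), list(a), function(g) list(g * s))
}

# Elementwise max/min; ties route the gradient to the first argument.
ad_pmax <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  m <- a$value >= b$value
  ad_node(pmax(a$value, b$value), list(a, b),
          function(g) list(g * m, g * (!m)))
}

ad_pmin <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  m <- a$value <= b$value
  ad_node(pmin(a$value, b$value), list(a, b),
          function(g) list(g * m, g * (!m)))
}

ad_clamp_min <- function(a, k) {
  a <- as_ad(a)
  m <- a$value >= k
  ad_node(pmax(a$value, k), list(a), function(g) list(g * m))
}

## ---- reductions -----------------------------------------------------------

ad_sum <- function(a) {
  a <- as_ad(a)
  d <- if (is.null(dim(a$value))) length(a$value) else dim(a$value)
  ad_node(sum(a$value), list(a), function(g) list(array(as.numeric(g), dim = d)))
}

ad_mean <- function(a) {
  a <- as_ad(a)
  n <- length(a$value)
  d <- if (is.null(dim(a$value))) n else dim(a$value)
  ad_node(mean(a$value), list(a),
          function(g) list(array(as.numeric(g) / n, dim = d)))
}

## ---- linear algebra -------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value %*% b$value, list(a, b),
          function(g) list(g %*% t(b$value), t(a$value) %*% g))
}

ad_t <- function(a) {
  a <- as_ad(a)
  ad_node(t(a$value), list(a), function(g) list(t(g)))
}

# Add a length-d vector to every row of an n x d matrix.
ad_add_rowvec <- function(x, b) {
  x <- as_ad(x); b <- as_ad(b)
  ad_node(sweep(x$value, 2, b$value, "+"), list(x, b),
          function(g) list(g, colSums(g)))
}

ad_linear <- function(x, w, b = NULL) {
  out <- ad_matmul(x, w)
  if (!is.null(b)) out <- ad_add_rowvec(out, b) else out
}

ad_rows <- function(x, idx) {
  x <- as_ad(x)
  d <- dim(x$value)
  ad_node(x$value[idx, , drop = FALSE], list(x), function(g) {
    dx <- array(0, dim = d)
    for (j in seq_along(idx)) dx[idx[j], ] <- dx[idx[j], ] + g[j, ]
    list(dx)
  })
}

ad_cols <- function(x, idx) {
  x <- as_ad(x)
  d <- dim(x$value)
  ad_node(x$value[, idx, drop = FALSE], list(x), function(g) {
    dx <- array(0, dim = d)
    for (j in seq_along(idx)) dx[, idx[j]] <- dx[, idx[j]] + g[, j]
    list(dx)
  })
}

ad_softmax_rows <- function(x) {
  x <- as_ad(x)
  v <- x$value - apply(x$value, 1, max)
  e <- exp(v)
  s <- e / rowSums(e)
  ad_node(s, list(x), function(g) {
    dot <- rowSums(g * s)
    list(s * (g - dot))
  })
}

## ---- image/tensor ops (arrays stored C x H x W) ---------------------------

# im2col for a (C,H,W) array with k x k kernel, given padding and stride 1.
# Rows are grouped by kernel offset, channels fastest within an offset.
.im2col <- function(xpad, C, H, W, k) {
  blocks <- vector("list", k * k)
  idx <- 1L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      sl <- xpad[, di:(di + H - 1L), dj:(dj + W - 1L), drop = FALSE]
      dim(sl) <- c(C, H * W)
      blocks[[idx]] <- sl
      idx <- idx + 1L
    }
  }
  do.call(rbind, blocks)
}

.col2im <- function(dcols, C, H, W, k, pad) {
  dxpad <- array(0, dim = c(C, H + 2L * pad, W + 2L * pad))
  idx <- 1L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      block <- dcols[((idx - 1L) * C + 1L):(idx * C), , drop = FALSE]
      dim(block) <- c(C, H, W)
      dxpad[, di:(di + H - 1L), dj:(dj + W - 1L)] <-
        dxpad[, di:(di + H - 1L), dj:(dj + W - 1L)] + block
      idx <- idx + 1L
    }
  }
  if (pad > 0L) {
    dxpad[, (pad + 1L):(pad + H), (pad + 1L):(pad + W), drop = FALSE]
  } else dxpad
}

# Flatten conv weights (Co, Ci, k, k) to the (Co, Ci*k*k) layout matching
# .im2col's row order.
.wmat <- function(w) {
  d <- dim(w)
  co <- d[1]; ci <- d[2]; k <- d[3]
  m <- matrix(0, co, ci * k * k)
  idx <- 1L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      m[, ((idx - 1L) * ci + 1L):(idx * ci)] <- w[, , di, dj]
      idx <- idx + 1L
    }
  }
  m
}

.wmat_back <- function(dm, co, ci, k) {
  dw <- array(0, dim = c(co, ci, k, k))
  idx <- 1L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      dw[, , di, dj] <- dm[, ((idx - 1L) * ci + 1L):(idx * ci)]
      idx <- idx + 1L
    }
  }
  dw
}

# 2-D convolution, stride 1, 'same' padding for odd k when pad = (k-1)/2.
# x: (Ci,H,W); w: (Co,Ci,k,k); b: length Co or NULL.
ad_conv2d <- function(x, w, b = NULL, pad = NULL) {
  x <- as_ad(x); w <- as_ad(w)
  if (!is.null(b)) b <- as_ad(b)
  dw <- dim(w$value)
  co <- dw[1]; ci <- dw[2]; k <- dw[3]
  dx <- dim(x$value)
  C <- dx[1]; H <- dx[2]; W <- dx[3]
  stopifnot(C == ci)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  xpad <- array(0, dim = c(C, H + 2L * pad, W + 2L * pad))
  xpad[, (pad + 1L):(pad + H), (pad + 1L):(pad + W)] <- x$value
  cols <- .im2col(xpad, C, H, W, k)
  wm <- .wmat(w$value)
  ym <- wm %*% cols
  if (!is.null(b)) ym <- ym + b$value
  y <- ym
  dim(y) <- c(co, H, W)
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  ad_node(y, parents, function(g) {
    gm <- g
    dim(gm) <- c(co, H * W)
    dwm <- gm %*% t(cols)
    dcols <- t(wm) %*% gm
    dxv <- .col2im(dcols, C, H, W, k, pad)
    out <- list(dxv, .wmat_back(dwm, co, ci, k))
    if (!is.null(b)) out <- c(out, list(rowSums(gm)))
    out
  })
}

# 2x2 average pooling; requires even H and W.
ad_avgpool2 <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; W <- d[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  h2 <- H %/% 2L; w2 <- W %/% 2L
  v <- (x$value[, seq(1, H, 2), seq(1, W, 2), drop = FALSE] +
        x$value[, seq(2, H, 2), seq(1, W, 2), drop = FALSE] +
        x$value[, seq(1, H, 2), seq(2, W, 2), drop = FALSE] +
        x$value[, seq(2, H, 2), seq(2, W, 2), drop = FALSE]) / 4
  dim(v) <- c(C, h2, w2)
  ad_node(v, list(x), function(g) {
    dx <- array(0, dim = d)
    gq <- g / 4
    dx[, seq(1, H, 2), seq(1, W, 2)] <- gq
    dx[, seq(2, H, 2), seq(1, W, 2)] <- dx[, seq(2, H, 2), seq(1, W, 2)] + gq
    dx[, seq(1, H, 2), seq(2, W, 2)] <- dx[, seq(1, H, 2), seq(2, W, 2)] + gq
    dx[, seq(2, H, 2), seq(2, W, 2)] <- dx[, seq(2, H, 2), seq(2, W, 2)] + gq
    list(dx)
  })
}

# Global average pool (C,H,W) -> length-C vector.
ad_gap <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value)
  C <- d[1]; n <- d[2] * d[3]
  m <- x$value
  dim(m) <- c(C, n)
  ad_node(rowMeans(m), list(x), function(g) {
    list(array(rep(g / n, times = n), dim = d))
  })
}

ad_concat_c <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[2:3] == db[2:3]))
  v <- array(0, dim = c(da[1] + db[1], da[2], da[3]))
  v[seq_len(da[1]), , ] <- a$value
  v[da[1] + seq_len(db[1]), , ] <- b$value
  ad_node(v, list(a, b), function(g) {
    list(g[seq_len(da[1]), , , drop = FALSE],
         g[da[1] + seq_len(db[1]), , , drop = FALSE])
  })
}

# Multiply (C,H,W) by a per-channel weight vector of length C.
ad_mul_channel <- function(x, w) {
  x <- as_ad(x); w <- as_ad(w)
  d <- dim(x$value)
  C <- d[1]
  stopifnot(length(w$value) == C)
  v <- x$value * w$value          # recycling over the first dim (C fastest)
  ad_node(v, list(x, w), function(g) {
    gx <- g * w$value
    gm <- g * x$value
    dim(gm) <- c(C, d[2] * d[3])
    list(gx, rowSums(gm))
  })
}

# Multiply (C,H,W) by a (1,H,W) spatial map broadcast over channels.
ad_mul_spatial <- function(x, s) {
  x <- as_ad(x); s <- as_ad(s)
  d <- dim(x$value); ds <- dim(s$value)
  stopifnot(ds[1] == 1L, ds[2] == d[2], ds[3] == d[3])
  sb <- aperm(array(s$value[1, , ], dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  ad_node(x$value * sb, list(x, s), function(g) {
    gx <- g * sb
    gs <- apply(g * x$value, c(2, 3), sum)
    dim(gs) <- c(1L, d[2], d[3])
    list(gx, gs)
  })
}

# 1-D interpolation weights from `n_in` samples onto `n_out` samples.
# Returns an n_out x n_in matrix; rows sum to 1.
.resize_weights_1d <- function(n_in, n_out, mode) {
  m <- matrix(0, n_out, n_in)
  if (mode == "nearest") {
    src <- pmin(n_in, floor((seq_len(n_out) - 1) * n_in / n_out) + 1L)
    m[cbind(seq_len(n_out), src)] <- 1
  } else if (mode == "bilinear") {
    # align-corners = FALSE convention
    pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
    pos <- pmin(pmax(pos, 0), n_in - 1)
    lo <- floor(pos)
    frac <- pos - lo
    lo <- as.integer(lo) + 1L
    hi <- pmin(lo + 1L, n_in)
    m[cbind(seq_len(n_out), lo)] <- m[cbind(seq_len(n_out), lo)] + (1 - frac)
    m[cbind(seq_len(n_out), hi)] <- m[cbind(seq_len(n_out), hi)] + frac
  } else stop("unknown resize mode: ", mode)
  m
}

# Resize (C,H,W) to (C,outH,outW) by separable nearest/bilinear
# interpolation. Linear in x, so backward is the transposed map.
ad_resize <- function(x, out_h, out_w, mode = "nearest") {
  x <- as_ad(x)
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; W <- d[3]
  mh <- .resize_weights_1d(H, out_h, mode)   # out_h x H
  mw <- .resize_weights_1d(W, out_w, mode)   # out_w x W
  resize_fwd <- function(arr) {
    out <- array(0, dim = c(C, out_h, out_w))
    for (cc in seq_len(C)) out[cc, , ] <- mh %*% arr[cc, , ] %*% t(mw)
    out
  }
  ad_node(resize_fwd(x$value), list(x), function(g) {
    dx <- array(0, dim = d)
    for (cc in seq_len(C)) dx[cc, , ] <- t(mh) %*% g[cc, , ] %*% mw
    list(dx)
  })
}

# Stack two matrices vertically.
ad_rbind <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  na <- nrow(a$value)
  ad_node(rbind(a$value, b$value), list(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE],
         g[(na + 1):nrow(g), , drop = FALSE])
  })
}

# Reshape (C,H,W) to an (H*W) x C matrix of per-position feature rows
# (spatial positions in column-major order, matching flattenMemory).
ad_flatten_hw <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value)
  v <- x$value
  dim(v) <- c(d[1], d[2] * d[3])
  ad_node(t(v), list(x), function(g) {
    dx <- t(g)
    dim(dx) <- d
    list(dx)
  })
}

## ---- optimiser ------------------------------------------------------------

# AdamW with decoupled weight decay and global-norm gradient clipping.
adamw_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value))),
       v = lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(params, state, lr = 2e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4, clip_norm = 0.1) {
  grads <- lapply(params, function(p) {
    if (is.null(p$grad)) array(0, dim = dim(p$value) %||% length(p$value)) else p$grad
  })
  if (is.finite(clip_norm) && clip_norm > 0) {
    total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (total > clip_norm) grads <- lapply(grads, function(g) g * (clip_norm / total))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mh <- state$m[[i]] / bc1
    vh <- state$v[[i]] / bc2
    od <- dim(params[[i]]$value)
    upd <- params[[i]]$value -
      lr * (mh / (sqrt(vh) + eps) + weight_decay * params[[i]]$value)
    dim(upd) <- od   # keep plain vectors plain
    params[[i]]$value <- upd
  }
  state
}
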