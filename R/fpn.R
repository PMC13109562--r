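#' Multi-level feature pyramid container
#'
#' Ordered multi-channel feature grids, highest resolution first. Each level
#' is a numeric array with dimensions \code{(C, H, W)}; spatial dimensions
#' halve (floor) between consecutive levels and all levels share the channel
#' count.
#'
#' @slot levels list of \code{(C, H, W)} numeric arrays.
#' @exportClass FeaturePyramid
setClass("FeaturePyramid", representation(levels = "list"),
         validity = function(object) {
           lv <- object@levels
           if (length(lv) == 0) return("pyramid needs at least one level")
           dims <- lapply(lv, dim)
           for (d in dims) {
             if (length(d) != 3) return("levels must be (C,H,W) arrays")
             if (any(d < 1)) return("all dimensions must be >= 1")
           }
           C <- dims[[1]][1]
           for (i in seq_along(dims)) {
             if (dims[[i]][1] != C) return("all levels must share the channel count")
             if (i > 1) {
               if (dims[[i]][2] != dims[[i - 1]][2] %/% 2 ||
                   dims[[i]][3] != dims[[i - 1]][3] %/% 2)
                 return("spatial dims must halve (floor) between levels")
             }
           }
           if (!all(vapply(lv, function(x) all(is.finite(x)), logical(1))))
             return("levels must be finite")
           TRUE
         })

#' Construct a FeaturePyramid
#' @param levels list of \code{(C,H,W)} arrays, highest resolution first.
#' @return A \code{\linkS4class{FeaturePyramid}}.
#' @export
featurePyramid <- function(levels) new("FeaturePyramid", levels = levels)

#' @describeIn featurePyramid list of level arrays.
#' @param object a \code{FeaturePyramid}.
#' @export
setGeneric("pyramidLevels", function(object) standardGeneric("pyramidLevels"))

#' @rdname featurePyramid
#' @export
setMethod("pyramidLevels", "FeaturePyramid", function(object) object@levels)

#' @describeIn featurePyramid number of levels.
#' @export
setGeneric("nLevels", function(object) standardGeneric("nLevels"))

#' @rdname featurePyramid
#' @export
setMethod("nLevels", "FeaturePyramid", function(object) length(object@levels))

setMethod("show", "FeaturePyramid", function(object) {
  cat("FeaturePyramid with", length(object@levels), "level(s):\n")
  for (i in seq_along(object@levels)) {
    d <- dim(object@levels[[i]])
    cat(sprintf("  level %d: C=%d H=%d W=%d\n", i, d[1], d[2], d[3]))
  }
})

## ---- parameters -----------------------------------------------------------

.conv_w <- function(co, ci, k, sd) array(stats::rnorm(co * ci * k * k, sd = sd),
                                         dim = c(co, ci, k, k))

#' Initialise progressive-FPN parameters
#'
#' Parameters of the top-level transform (position-wise linear, 3x3
#' convolution, position-wise linear) and, for each of the
#' \code{nLevels - 1} fusion steps, of the adaptive feature aggregation
#' operator: two 1x1 C-to-1 spatial-gate convolutions, a 2C-to-2C channel
#' weighting layer on pooled features, and a 1x1 2C-to-C reduction.
#'
#' @param C channel count of the (projected) pyramid.
#' @param nLevels number of pyramid levels.
#' @param seed RNG seed for the initial weights.
#' @param sd standard deviation of the normal weight initialisation.
#' @return nested list of weight/bias arrays.
#' @export
pfpnParams <- function(C, nLevels, seed = 1L, sd = 0.1) {
  stopifnot(nLevels >= 1)
  set.seed(seed)
  top <- list(mlp1_w = .conv_w(C, C, 1, sd), mlp1_b = numeric(C),
              conv_w = .conv_w(C, C, 3, sd), conv_b = numeric(C),
              mlp2_w = .conv_w(C, C, 1, sd), mlp2_b = numeric(C))
  afa <- lapply(seq_len(max(nLevels - 1, 0)), function(i) {
    list(sp1_w = .conv_w(1, C, 1, sd), sp1_b = numeric(1),
         sp2_w = .conv_w(1, C, 1, sd), sp2_b = numeric(1),
         ch_w = matrix(stats::rnorm(4 * C * C, sd = sd), 2 * C, 2 * C),
         ch_b = numeric(2 * C),
         red_w = .conv_w(C, 2 * C, 1, sd), red_b = numeric(C))
  })
  list(C = C, nLevels = nLevels, top = top, afa = afa)
}

# Wrap a parameter list's leaf arrays in autodiff nodes (params when
# trainable = TRUE, constants otherwise). Preserves the nesting; skips
# scalar bookkeeping fields (C, nLevels).
.wrap_params <- function(p, trainable = FALSE) {
  wrap <- function(x) {
    if (is.list(x)) lapply(x, wrap)
    else if (trainable) ad_param(x) else ad_const(x)
  }
  keep <- setdiff(names(p), c("C", "nLevels"))
  if (!is.null(names(p)) && length(keep) < length(p)) p <- p[keep]
  wrap(p)
}

## ---- autodiff forward passes ---------------------------------------------

.top_transform_ad <- function(x, tp) {
  h <- ad_conv2d(x, tp$mlp1_w, tp$mlp1_b)      # position-wise linear
  h <- ad_conv2d(h, tp$conv_w, tp$conv_b)      # 3x3, padding preserves H,W
  ad_conv2d(h, tp$mlp2_w, tp$mlp2_b)           # position-wise linear
}

.afa_spatial_ad <- function(p1, p2, ap) {
  ad_sigmoid(ad_add(ad_conv2d(p1, ap$sp1_w, ap$sp1_b),
                    ad_conv2d(p2, ap$sp2_w, ap$sp2_b)))
}

.afa_channel_ad <- function(p1, p2, ap) {
  p12 <- ad_concat_c(p1, p2)                       # 2C channels
  pooled <- ad_gap(p12)                            # length 2C
  # channel weights: Sigmoid(Conv(AvgPool(P12))) -- a 2C->2C linear map
  z <- ad_matmul(ad_t(ad_node_vec_as_col(pooled)), ad_t(ap$ch_w))
  pc <- ad_sigmoid(ad_add_rowvec(z, ap$ch_b))      # 1 x 2C
  pcv <- ad_as_vector(pc)
  gated <- ad_mul_channel(p12, pcv)                # Pc (x) P12
  list(fc = ad_conv2d(gated, ap$red_w, ap$red_b),  # 1x1 2C->C reduction
       pc = pcv)
}

# small helpers for vector/matrix plumbing inside the channel gate
ad_node_vec_as_col <- function(v) {
  v <- as_ad(v)
  n <- length(v$value)
  ad_node(matrix(v$value, n, 1), list(v), function(g) list(as.numeric(g)))
}

ad_as_vector <- function(m) {
  m <- as_ad(m)
  d <- dim(m$value)
  ad_node(as.numeric(m$value), list(m), function(g) list(array(g, dim = d)))
}

.afa_fuse_ad <- function(p1, p2, ap) {
  fs <- .afa_spatial_ad(p1, p2, ap)
  ch <- .afa_channel_ad(p1, p2, ap)
  ad_mul_spatial(ch$fc, fs)                        # P = Fc (x) Fs
}

.pfpn_forward_ad <- function(level_nodes, pw, upsampleMode = "nearest") {
  n <- length(level_nodes)
  out <- vector("list", n)
  out[[n]] <- .top_transform_ad(level_nodes[[n]], pw$top)
  if (n >= 2) {
    for (i in seq(n - 1, 1)) {
      d <- dim(level_nodes[[i]]$value)
      up <- ad_resize(out[[i + 1]], d[2], d[3], mode = upsampleMode)
      out[[i]] <- .afa_fuse_ad(level_nodes[[i]], up, pw$afa[[i]])
    }
  }
  out
}

## ---- exported numeric surface ---------------------------------------------

#' Top-level pyramid transform
#'
#' The highest-resolution output level is produced by a feed-forward
#' composition: position-wise linear, 3x3 convolution (padding preserving
#' H and W), position-wise linear. Shape is preserved.
#'
#' @param x \code{(C,H,W)} numeric array.
#' @param params parameter list from \code{\link{pfpnParams}}.
#' @return \code{(C,H,W)} numeric array.
#' @export
topTransform <- function(x, params) {
  if (dim(x)[1] != params$C) stop("channel mismatch with configured C")
  ad_value(.top_transform_ad(ad_const(x), .wrap_params(params$top)))
}

#' Adaptive feature aggregation: spatial gate
#'
#' \code{Fs = Sigmoid(Conv(P1) + Conv(P2))} with 1x1 C-to-1 convolutions:
#' a single-channel map of values strictly in (0,1) highlighting prominent
#' spatial regions.
#'
#' @param p1,p2 \code{(C,H,W)} arrays of identical shape.
#' @param params parameter list from \code{\link{pfpnParams}}.
#' @param step which fusion step's parameters to use (1-based).
#' @return \code{(1,H,W)} array with entries in (0,1).
#' @export
afaSpatialGate <- function(p1, p2, params, step = 1) {
  .check_same_shape(p1, p2)
  ad_value(.afa_spatial_ad(ad_const(p1), ad_const(p2),
                           .wrap_params(params$afa[[step]])))
}

#' Adaptive feature aggregation: channel gate
#'
#' P1 and P2 are concatenated to 2C channels; global average pooling, a
#' linear layer and a sigmoid produce per-channel weights Pc in (0,1); the
#' weighted features are reduced back to C channels by a 1x1 convolution.
#'
#' @inheritParams afaSpatialGate
#' @return \code{(C,H,W)} array F_c; the length-2C channel weights are
#'   attached as attribute \code{"channelWeights"}.
#' @export
afaChannelGate <- function(p1, p2, params, step = 1) {
  .check_same_shape(p1, p2)
  ch <- .afa_channel_ad(ad_const(p1), ad_const(p2),
                        .wrap_params(params$afa[[step]]))
  out <- ad_value(ch$fc)
  attr(out, "channelWeights") <- ad_value(ch$pc)
  out
}

#' Adaptive feature aggregation: fused output
#'
#' \code{P = Fc (x) Fs}: the channel-gated features modulated elementwise by
#' the broadcast single-channel spatial gate.
#'
#' @inheritParams afaSpatialGate
#' @return \code{(C,H,W)} array.
#' @export
afaFuse <- function(p1, p2, params, step = 1) {
  .check_same_shape(p1, p2)
  ad_value(.afa_fuse_ad(ad_const(p1), ad_const(p2),
                        .wrap_params(params$afa[[step]])))
}

.check_same_shape <- function(p1, p2) {
  if (!identical(dim(p1), dim(p2))) stop("P1 and P2 must have the same shape")
}

#' Progressive top-down pyramid fusion
#'
#' The top level goes through \code{\link{topTransform}}; every lower level
#' i is \code{AFA(Level_i, Upsample(Level_(i+1)'))}, strictly sequentially
#' from the top down, so each output level depends on all levels above it.
#' Upsampling interpolates to the exact H x W of the receiving level
#' (factor two for a standard pyramid), which also absorbs odd-size
#' mismatches.
#'
#' @param pyramid a \code{\linkS4class{FeaturePyramid}}.
#' @param params parameter list from \code{\link{pfpnParams}}.
#' @param upsampleMode \code{"nearest"} (default) or \code{"bilinear"}.
#' @return A \code{\linkS4class{FeaturePyramid}} with the same shapes.
#' @export
progressiveFuse <- function(pyramid, params, upsampleMode = "nearest") {
  lv <- pyramidLevels(pyramid)
  if (dim(lv[[1]])[1] != params$C) stop("channel mismatch with configured C")
  nodes <- lapply(lv, ad_const)
  out <- .pfpn_forward_ad(nodes, .wrap_params(params), upsampleMode)
  featurePyramid(lapply(out, ad_value))
}

#' Finite-difference validation of progressive fusion gradients
#'
#' Runs the full progressive fusion on a seeded random pyramid, takes the
#' sum of all output levels as a scalar objective, and compares analytic
#' reverse-mode gradients against central finite differences at a random
#' sample of input and parameter coordinates.
#'
#' @param C,shapes channel count and list of \code{c(H, W)} per level.
#' @param probes number of coordinates to probe.
#' @param seed RNG seed (pyramid content, parameters, probe choice).
#' @param eps finite-difference step.
#' @param upsampleMode passed to the fusion.
#' @return maximum symmetric relative error across probes.
#' @export
checkPfpnGradients <- function(C = 8, shapes = list(c(16, 16), c(8, 8)),
                               probes = 30, seed = 1L, eps = 1e-5,
                               upsampleMode = "nearest") {
  set.seed(seed)
  lv <- lapply(shapes, function(s) array(stats::rnorm(C * s[1] * s[2], sd = 0.5),
                                         dim = c(C, s[1], s[2])))
  params <- pfpnParams(C, length(shapes), seed = seed + 1L)
  input_nodes <- lapply(lv, ad_param)
  pw <- .wrap_params(params, trainable = TRUE)
  objective_nodes <- function(inodes, pwraps) {
    outs <- .pfpn_forward_ad(inodes, pwraps, upsampleMode)
    s <- ad_sum(outs[[1]])
    if (length(outs) > 1)
      for (i in 2:length(outs)) s <- ad_add(s, ad_sum(outs[[i]]))
    s
  }
  root <- objective_nodes(input_nodes, pw)
  ad_backward(root)

  leaves <- c(input_nodes, .flatten_params(pw))
  numeric_forward <- function() {
    ad_value(objective_nodes(lapply(input_nodes, function(n) ad_const(n$value)),
                             .wrap_leaf_values(pw)))
  }
  max_err <- 0
  for (p in seq_len(probes)) {
    leaf <- leaves[[sample.int(length(leaves), 1)]]
    idx <- sample.int(length(leaf$value), 1)
    orig <- leaf$value[idx]
    leaf$value[idx] <- orig + eps
    up <- numeric_forward()
    leaf$value[idx] <- orig - eps
    dn <- numeric_forward()
    leaf$value[idx] <- orig
    fd <- (up - dn) / (2 * eps)
    an <- if (is.null(leaf$grad)) 0 else leaf$grad[idx]
    denom <- max(abs(fd) + abs(an), 1e-4)
    max_err <- max(max_err, abs(fd - an) / denom)
  }
  max_err
}

.flatten_params <- function(pw) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "adNode")) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (e in x) walk(e)
  }
  walk(pw)
  out
}

.wrap_leaf_values <- function(pw) {
  rapply2 <- function(x) {
    if (inherits(x, "adNode")) ad_const(x$value)
    else if (is.list(x)) lapply(x, rapply2)
    else x
  }
  rapply2(pw)
}
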