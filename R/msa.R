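# Multi-scale attention (MSA) encoder.
#
# The MSA layer builds an attention map from a local 3x3 convolution plus
# three strip-convolution branches (pairs of kx1 / 1xk depth-wise kernels,
# k = 5/7/11 by default) applied to a shared depth-wise convolution of the
# input, mixes them with a 1x1 convolution, and reweights the input by
# element-wise multiplication:
#   Att = Conv1x1( Conv3x3(F) + sum_i Branch_i(DWConv(F)) ),  Out = Att * F.
# An MSA block is Conv3x3 -> batch norm -> ReLU -> MSA layer; the encoder
# stacks one block per resolution level with a downsampling operator between
# levels, producing feature maps at sides input/1, /2, /4, /8, /16.

init_msa_layer <- function(channels, cfg) {
  k <- cfg$shared_dw_kernel
  list(
    local = list(w = he_conv(3L, 3L, channels, channels),
                 b = numeric(channels)),
    dw = list(w = he_dw(k, k, channels), b = numeric(channels)),
    br = lapply(cfg$branch_kernels, function(bk) {
      list(v = list(w = he_dw(bk, 1L, channels), b = numeric(channels)),
           h = list(w = he_dw(1L, bk, channels), b = numeric(channels)))
    }),
    mix = list(w = glorot_mat(channels, channels), b = numeric(channels))
  )
}

init_msa_block <- function(cin, cout, cfg) {
  list(conv = list(w = he_conv(3L, 3L, cin, cout), b = numeric(cout)),
       bn = list(gamma = rep(1, cout), beta = numeric(cout),
                 rm = numeric(cout), rv = rep(1, cout)),
       msa = init_msa_layer(cout, cfg))
}

init_encoder <- function(cfg) {
  ch <- cfg$stage_channels
  stages <- vector("list", 5L)
  for (l in 1:5) {
    cin <- if (l == 1L) 1L else ch[l - 1L]
    down <- NULL
    if (l > 1L && cfg$downsample == "conv") {
      down <- list(w = he_conv(3L, 3L, cin, cin), b = numeric(cin))
    }
    stages[[l]] <- list(down = down, block = init_msa_block(cin, ch[l], cfg))
  }
  stages
}

## ---- batched internals ----------------------------------------------------

msa_layer_fwd_b <- function(x, p) {
  f_local <- conv2d_fwd(x, p$local$w, p$local$b)
  f_dw <- dwconv_fwd(x, p$dw$w, p$dw$b)
  s <- f_local$out
  f_br <- vector("list", length(p$br))
  for (i in seq_along(p$br)) {
    fv <- dwconv_fwd(f_dw$out, p$br[[i]]$v$w, p$br[[i]]$v$b)
    fh <- dwconv_fwd(fv$out, p$br[[i]]$h$w, p$br[[i]]$h$b)
    s <- s + fh$out
    f_br[[i]] <- list(v = fv$cache, h = fh$cache)
  }
  f_mix <- conv1x1_fwd(s, p$mix$w, p$mix$b)
  att <- f_mix$out
  list(out = att * x,
       cache = list(x = x, att = att, local = f_local$cache, dw = f_dw$cache,
                    br = f_br, mix = f_mix$cache))
}

msa_layer_bwd_b <- function(dy, p, cache) {
  datt <- dy * cache$x
  dx <- dy * cache$att
  b_mix <- conv1x1_bwd(datt, cache$mix)
  ds <- b_mix$dx
  b_local <- conv2d_bwd(ds, cache$local)
  dx <- dx + b_local$dx
  dshared <- 0
  g_br <- vector("list", length(p$br))
  for (i in seq_along(p$br)) {
    b_h <- dwconv_bwd(ds, cache$br[[i]]$h)
    b_v <- dwconv_bwd(b_h$dx, cache$br[[i]]$v)
    dshared <- dshared + b_v$dx
    g_br[[i]] <- list(v = list(w = b_v$dw, b = b_v$db),
                      h = list(w = b_h$dw, b = b_h$db))
  }
  b_dw <- dwconv_bwd(dshared, cache$dw)
  dx <- dx + b_dw$dx
  list(dx = dx,
       grads = list(local = list(w = b_local$dw, b = b_local$db),
                    dw = list(w = b_dw$dw, b = b_dw$db),
                    br = g_br,
                    mix = list(w = b_mix$dw, b = b_mix$db)))
}

# conv -> BN -> ReLU -> MSA layer; returns updated BN running stats
msa_block_fwd_b <- function(x, p, training, momentum = 0.1) {
  f_conv <- conv2d_fwd(x, p$conv$w, p$conv$b)
  f_bn <- bnrelu_fwd(f_conv$out, p$bn$gamma, p$bn$beta, p$bn$rm, p$bn$rv,
                     training, momentum)
  f_msa <- msa_layer_fwd_b(f_bn$out, p$msa)
  list(out = f_msa$out,
       cache = list(conv = f_conv$cache, bn = f_bn$cache, msa = f_msa$cache),
       bn_stats = list(rm = f_bn$rm, rv = f_bn$rv))
}

msa_block_bwd_b <- function(dy, p, cache) {
  b_msa <- msa_layer_bwd_b(dy, p$msa, cache$msa)
  b_bn <- bnrelu_bwd(b_msa$dx, cache$bn)
  b_conv <- conv2d_bwd(b_bn$dx, cache$conv)
  list(dx = b_conv$dx,
       grads = list(conv = list(w = b_conv$dw, b = b_conv$db),
                    bn = list(gamma = b_bn$dgamma, beta = b_bn$dbeta),
                    msa = b_msa$grads))
}

encoder_fwd_b <- function(x, stages, cfg, training = FALSE) {
  feats <- vector("list", 5L)
  caches <- vector("list", 5L)
  bn_stats <- vector("list", 5L)
  h <- x
  for (l in 1:5) {
    p <- stages[[l]]
    dcache <- NULL
    if (l > 1L) {
      if (cfg$downsample == "conv") {
        fd <- conv2d_fwd(h, p$down$w, p$down$b, stride = 2L)
        h <- fd$out; dcache <- fd$cache
      } else {
        fd <- maxpool2_fwd(h)
        h <- fd$out; dcache <- fd$cache
      }
    }
    fb <- msa_block_fwd_b(h, p$block, training, cfg$bn_momentum)
    h <- fb$out
    feats[[l]] <- h
    caches[[l]] <- list(down = dcache, block = fb$cache)
    bn_stats[[l]] <- fb$bn_stats
  }
  list(feats = feats, caches = caches, bn_stats = bn_stats)
}

# dfeats: list of gradients w.r.t. each level's output (NULL allowed)
encoder_bwd_b <- function(dfeats, stages, cfg, caches) {
  grads <- vector("list", 5L)
  dh <- NULL
  for (l in 5:1) {
    d <- dfeats[[l]]
    if (!is.null(dh)) d <- if (is.null(d)) dh else d + dh
    bb <- msa_block_bwd_b(d, stages[[l]]$block, caches[[l]]$block)
    dh_in <- bb$dx
    gdown <- NULL
    if (l > 1L) {
      if (cfg$downsample == "conv") {
        bd <- conv2d_bwd(dh_in, caches[[l]]$down)
        dh <- bd$dx
        gdown <- list(w = bd$dw, b = bd$db)
      } else {
        dh <- maxpool2_bwd(dh_in, caches[[l]]$down)
      }
    } else {
      dh <- dh_in
    }
    grads[[l]] <- list(down = gdown, block = bb$grads)
  }
  list(dx = dh, grads = grads)
}

## ---- exported single-sample surface ---------------------------------------

#' Create parameters for one multi-scale attention layer
#'
#' Weights are drawn from the current R random stream (He initialization for
#' convolutions); seed control is up to the caller.
#'
#' @param channels channel count the layer preserves.
#' @param cfg an [mtsa_config()]; supplies branch and shared kernel sizes.
#' @return a nested parameter list.
#' @export
msa_layer_params <- function(channels, cfg = mtsa_config()) {
  init_msa_layer(channels, cfg)
}

#' Multi-scale attention layer forward pass
#'
#' Computes \code{Att = Conv1x1(Conv3x3(F) + sum_i Branch_i(DWConv(F)))} and
#' returns \code{Att * F} (element-wise). Shape-preserving.
#'
#' @param f feature map, array (rows x cols x channels).
#' @param params parameters from [msa_layer_params()].
#' @return array of the same shape as \code{f}.
#' @export
msa_layer_forward <- function(f, params) {
  stopifnot(length(dim(f)) == 3L)
  if (dim(f)[3] != dim(params$local$w)[3])
    stop("channel mismatch: map has ", dim(f)[3], " channels, params expect ",
         dim(params$local$w)[3])
  out <- msa_layer_fwd_b(array(f, c(1L, dim(f))), params)$out
  array(out[1, , , ], dim(f))
}

#' MSA block forward pass (conv / batch norm / ReLU / MSA layer)
#'
#' @param f feature map, array (rows x cols x channels_in).
#' @param params block parameters (see [mtsa_net()] internals or
#'   \code{mtsanet:::init_msa_block}).
#' @param training logical; batch statistics vs running averages.
#' @return array (rows x cols x channels_out).
#' @export
msa_block_forward <- function(f, params, training = FALSE) {
  stopifnot(length(dim(f)) == 3L)
  out <- msa_block_fwd_b(array(f, c(1L, dim(f))), params, training)$out
  array(out[1, , , ], dim(out)[2:4])
}

#' Encoder forward pass
#'
#' Runs a square image through the five-level MSA encoder and returns the
#' per-level feature maps with spatial sides input/1, /2, /4, /8, /16 and
#' channel counts \code{stage_channels}.
#'
#' @param image numeric matrix, square, side divisible by 16.
#' @param model an [mtsa_net()] object (or a bare encoder parameter list
#'   paired with a \code{cfg} argument).
#' @param cfg configuration; defaults to \code{model$config}.
#' @param training logical batch-norm mode.
#' @return list of 5 arrays (rows x cols x channels), level 0 first.
#' @export
encoder_forward <- function(image, model, cfg = NULL, training = FALSE) {
  if (inherits(model, "mtsa_net")) {
    cfg <- model$config
    stages <- model$params$enc
  } else {
    stages <- model
    if (is.null(cfg)) stop("cfg required when passing bare encoder params")
  }
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be a square matrix")
  if (nrow(image) %% 16L != 0L)
    stop("image side ", nrow(image), " not divisible by 16")
  x <- array(image, c(1L, dim(image), 1L))
  ef <- encoder_fwd_b(x, stages, cfg, training)
  lapply(ef$feats, function(fm) array(fm[1, , , ], dim(fm)[2:4]))
}
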