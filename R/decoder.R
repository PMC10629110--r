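# Segmentation decoder: four cascaded up-blocks (stride-2 transposed
# convolution, skip concatenation, 3x3 convolution + batch norm + ReLU)
# followed by a 1x1 convolution and a sigmoid, producing a full-resolution
# foreground probability map.

init_up_block <- function(cin, cskip, cfg) {
  list(tconv = list(w = he_conv(2L, 2L, cin, cskip), b = numeric(cskip)),
       conv = list(w = he_conv(3L, 3L, 2L * cskip, cskip), b = numeric(cskip)),
       bn = list(gamma = rep(1, cskip), beta = numeric(cskip),
                 rm = numeric(cskip), rv = rep(1, cskip)))
}

init_decoder <- function(cfg) {
  ch <- cfg$stage_channels
  ups <- vector("list", 4L)
  for (i in 1:4) {                    # block i: level 5-i+1 -> level 5-i
    ups[[i]] <- init_up_block(ch[6L - i], ch[5L - i], cfg)
  }
  # output bias starts at the logit of a ~5% foreground prior so the
  # sigmoid begins near the true lesion fraction instead of 0.5 (the
  # standard initialization for rare-foreground focal-loss heads)
  list(ups = ups,
       final = list(w = matrix(stats::rnorm(ch[1], sd = sqrt(2 / ch[1]))),
                    b = log(0.05 / 0.95)))
}

up_block_fwd_b <- function(x, skip, p, training, momentum = 0.1) {
  f_t <- tconv2_fwd(x, p$tconv$w, p$tconv$b)
  if (!identical(dim(f_t$out)[2:3], dim(skip)[2:3]))
    stop("resolution mismatch: upsampled ",
         paste(dim(f_t$out)[2:3], collapse = "x"), " vs skip ",
         paste(dim(skip)[2:3], collapse = "x"))
  cskip <- dim(skip)[4]
  fused <- array(0, c(dim(skip)[1:3], dim(f_t$out)[4] + cskip))
  fused[, , , seq_len(dim(f_t$out)[4])] <- f_t$out
  fused[, , , dim(f_t$out)[4] + seq_len(cskip)] <- skip
  f_c <- conv2d_fwd(fused, p$conv$w, p$conv$b)
  f_bn <- bnrelu_fwd(f_c$out, p$bn$gamma, p$bn$beta, p$bn$rm, p$bn$rv,
                     training, momentum)
  list(out = f_bn$out,
       cache = list(t = f_t$cache, c = f_c$cache, bn = f_bn$cache,
                    cup = dim(f_t$out)[4], cskip = cskip),
       bn_stats = list(rm = f_bn$rm, rv = f_bn$rv))
}

up_block_bwd_b <- function(dy, p, cache) {
  cc <- cache
  b_bn <- bnrelu_bwd(dy, cc$bn)
  b_c <- conv2d_bwd(b_bn$dx, cc$c)
  dfused <- b_c$dx
  dup <- dfused[, , , seq_len(cc$cup), drop = FALSE]
  dskip <- dfused[, , , cc$cup + seq_len(cc$cskip), drop = FALSE]
  b_t <- tconv2_bwd(dup, cc$t)
  list(dx = b_t$dx, dskip = dskip,
       grads = list(tconv = list(w = b_t$dw, b = b_t$db),
                    conv = list(w = b_c$dw, b = b_c$db),
                    bn = list(gamma = b_bn$dgamma, beta = b_bn$dbeta)))
}

# feats: list of 5 batched maps (level 0..4); returns (N,H,W) probabilities
decoder_fwd_b <- function(feats, p, training = FALSE, momentum = 0.1) {
  h <- feats[[5]]
  caches <- vector("list", 4L)
  bn_stats <- vector("list", 4L)
  for (i in 1:4) {
    fb <- up_block_fwd_b(h, feats[[5L - i]], p$ups[[i]], training, momentum)
    h <- fb$out
    caches[[i]] <- fb$cache
    bn_stats[[i]] <- fb$bn_stats
  }
  f_f <- conv1x1_fwd(h, p$final$w, p$final$b)
  z <- f_f$out
  dim(z) <- dim(f_f$out)[1:3]          # single output channel
  # clamp away from exact 0/1 (double sigmoid saturates beyond |z| ~ 36)
  prob <- pmin(pmax(sigmoid(z), 1e-7), 1 - 1e-7)
  list(prob = prob, cache = list(ups = caches, final = f_f$cache, prob = prob),
       bn_stats = bn_stats)
}

# dz: gradient w.r.t. the pre-sigmoid logit map (N,H,W)
decoder_bwd_b <- function(dz, p, cache) {
  dz4 <- array(dz, c(dim(dz), 1L))
  b_f <- conv1x1_bwd(dz4, cache$final)
  dh <- b_f$dx
  g_ups <- vector("list", 4L)
  dskips <- vector("list", 5L)
  for (i in 4:1) {
    bb <- up_block_bwd_b(dh, p$ups[[i]], cache$ups[[i]])
    g_ups[[i]] <- bb$grads
    dskips[[5L - i]] <- bb$dskip
    dh <- bb$dx
  }
  dskips[[5L]] <- dh
  list(dfeats = dskips,
       grads = list(ups = g_ups, final = list(w = b_f$dw, b = b_f$db)))
}

## ---- exported surface -----------------------------------------------------

#' Single decoder up-block
#'
#' Upsamples \code{f} with a stride-2 transposed convolution, concatenates
#' the skip map along channels, and applies a 3x3 convolution, batch norm
#' and ReLU. The output lives at the skip's resolution.
#'
#' @param f feature map (rows x cols x channels) at level L.
#' @param skip feature map at level L-1; spatial side must be exactly twice
#'   that of \code{f}.
#' @param params up-block parameters.
#' @param training logical batch-norm mode.
#' @return array at the skip's resolution and channel width.
#' @export
upsample_block <- function(f, skip, params, training = FALSE) {
  if (any(dim(skip)[1:2] != 2L * dim(f)[1:2]))
    stop("resolution mismatch: skip must be exactly twice the input side (",
         paste(dim(f)[1:2], collapse = "x"), " -> ",
         paste(dim(skip)[1:2], collapse = "x"), ")")
  out <- up_block_fwd_b(array(f, c(1L, dim(f))), array(skip, c(1L, dim(skip))),
                        params, training)$out
  array(out[1, , , ], dim(out)[2:4])
}

#' Decode encoder features into a segmentation probability map
#'
#' Chains the four up-blocks from the deepest level back to full resolution,
#' then applies the 1x1 output convolution and a sigmoid.
#'
#' @param features list of 5 feature maps as returned by
#'   [encoder_forward()] (level 0 first).
#' @param model an [mtsa_net()] object.
#' @param training logical batch-norm mode.
#' @return numeric matrix of foreground probabilities in (0,1), same spatial
#'   size as the encoder input.
#' @export
decode <- function(features, model, training = FALSE) {
  stopifnot(inherits(model, "mtsa_net"))
  if (length(features) != 5L)
    stop("expected 5 feature maps, got ", length(features))
  fb <- lapply(features, function(f) array(f, c(1L, dim(f))))
  out <- decoder_fwd_b(fb, model$params$dec, training)
  matrix(out$prob[1, , ], dim(features[[1]])[1], dim(features[[1]])[2])
}
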