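# Low-level neural-network operations on batched tensors.
#
# Layout convention: a batch of feature maps is an array of dimension
# (N, H, W, C) — batch, rows, cols, channels. Dense convolutions are computed
# by im2col gathers followed by a single BLAS matrix multiply; depth-wise
# convolutions (square and strip kernels) use shift-and-accumulate over the
# padded input, which keeps memory flat. Every forward returns the output and
# a cache; the matching *_bwd consumes the cache and the upstream gradient.
# All backward passes are hand-derived and verified against finite
# differences in the test suite.

pad_spatial <- function(x, ph, pw) {
  d <- dim(x)
  if (ph == 0L && pw == 0L) return(x)
  xp <- array(0, c(d[1], d[2] + 2L * ph, d[3] + 2L * pw, d[4]))
  xp[, (ph + 1L):(ph + d[2]), (pw + 1L):(pw + d[3]), ] <- x
  xp
}

crop_spatial <- function(xp, ph, pw, H, W) {
  if (ph == 0L && pw == 0L) return(xp)
  xp[, (ph + 1L):(ph + H), (pw + 1L):(pw + W), , drop = FALSE]
}

# Linear indices into the padded (Hp x Wp) spatial plane for every
# (output position, kernel offset) pair; output rows vary fastest, matching
# column-major array layout.
conv_idx <- function(Hp, Wp, kh, kw, sh, sw) {
  Ho <- (Hp - kh) %/% sh + 1L
  Wo <- (Wp - kw) %/% sw + 1L
  oh <- rep(seq_len(Ho), times = Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  r0 <- (oh - 1L) * sh
  c0 <- (ow - 1L) * sw
  a <- rep(seq_len(kh), times = kw)
  b <- rep(seq_len(kw), each = kh)
  idx <- outer(r0, a, "+") + Hp * (outer(c0, b - 1L, "+"))
  storage.mode(idx) <- "integer"
  list(idx = idx, Ho = Ho, Wo = Wo)
}

## ---- dense 2-D convolution ------------------------------------------------

# x: (N,H,W,Cin); w: (kh,kw,Cin,Cout); bias: length Cout or NULL.
# pad NULL means "same" padding for odd kernels at stride 1, and the
# standard (k-1)/2 padding for stride 2 (halving even sides).
conv2d_fwd <- function(x, w, bias = NULL, stride = 1L, pad = NULL) {
  d <- dim(x)
  dw <- dim(w); kh <- dw[1]; kw <- dw[2]
  if (dw[3] != d[4]) stop("conv2d: input has ", d[4],
                          " channels, weights expect ", dw[3])
  if (is.null(pad)) pad <- c((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)
  r <- .conv2d_fwd_cpp(x, as.integer(d), w, as.integer(dw),
                       if (is.null(bias)) numeric(0) else bias,
                       as.integer(stride), as.integer(pad[1]),
                       as.integer(pad[2]))
  list(out = r$out,
       cache = list(xcol = r$xcol, xdim = as.integer(d), w = w,
                    stride = as.integer(stride), pad = as.integer(pad),
                    has_bias = !is.null(bias)))
}

conv2d_bwd <- function(dy, cache) {
  cc <- cache
  .conv2d_bwd_cpp(dy, cc$xcol, cc$xdim, cc$w,
                  as.integer(dim(cc$w)), cc$stride, cc$pad[1], cc$pad[2],
                  cc$has_bias)
}

## ---- depth-wise convolution (square or strip kernels) ---------------------

# w: (kh, kw, C); stride 1, "same" padding (odd kernel sides).
dwconv_fwd <- function(x, w, bias = NULL) {
  if (dim(w)[3] != dim(x)[4]) stop("dwconv: channel mismatch")
  r <- .dwconv_fwd_cpp(x, as.integer(dim(x)), w, as.integer(dim(w)),
                       if (is.null(bias)) numeric(0) else bias)
  list(out = r$out, cache = list(fx = r$fx, xdim = as.integer(dim(x)),
                                 w = w, has_bias = !is.null(bias)))
}

dwconv_bwd <- function(dy, cache) {
  cc <- cache
  .dwconv_bwd_cpp(dy, cc$fx, cc$xdim, cc$w,
                  as.integer(dim(cc$w)), cc$has_bias)
}

## ---- 1x1 convolution ------------------------------------------------------

conv1x1_fwd <- function(x, w, bias = NULL) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4])
  ymat <- m %*% w
  if (!is.null(bias)) ymat <- ymat + rep(bias, each = nrow(m))
  list(out = array(ymat, c(d[1:3], ncol(w))),
       cache = list(m = m, w = w, d = d, has_bias = !is.null(bias)))
}

conv1x1_bwd <- function(dy, cache) {
  cc <- cache
  dymat <- matrix(dy, nrow(cc$m), ncol(cc$w))
  list(dx = array(dymat %*% t(cc$w), cc$d),
       dw = crossprod(cc$m, dymat),
       db = if (cc$has_bias) colSums(dymat) else NULL)
}

## ---- batch normalization (per channel over N,H,W) -------------------------

bn_fwd <- function(x, gamma, beta, rm, rv, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); NHW <- prod(d[1:3]); C <- d[4]
  m <- matrix(x, NHW, C)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu * mu
    v <- pmax(v, 0)
    rm_new <- (1 - momentum) * rm + momentum * mu
    rv_new <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- rm; v <- rv; rm_new <- rm; rv_new <- rv
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (m - rep(mu, each = NHW)) * rep(invstd, each = NHW)
  y <- xhat * rep(gamma, each = NHW) + rep(beta, each = NHW)
  list(out = array(y, d),
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                    training = training),
       rm = rm_new, rv = rv_new)
}

bn_bwd <- function(dy, cache) {
  cc <- cache
  d <- cc$d; NHW <- prod(d[1:3]); C <- d[4]
  dym <- matrix(dy, NHW, C)
  dgamma <- colSums(dym * cc$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(cc$gamma, each = NHW)
  if (cc$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cc$xhat)
    dxm <- (dxhat - rep(s1 / NHW, each = NHW) -
              cc$xhat * rep(s2 / NHW, each = NHW)) * rep(cc$invstd, each = NHW)
  } else {
    dxm <- dxhat * rep(cc$invstd, each = NHW)
  }
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

## ---- fused batch-norm + ReLU (compiled) -----------------------------------

bnrelu_fwd <- function(x, gamma, beta, rm, rv, training, momentum = 0.1,
                       eps = 1e-5) {
  r <- .bnrelu_fwd_cpp(x, as.integer(dim(x)), gamma, beta, rm, rv,
                       training, momentum, eps)
  list(out = r$out,
       cache = list(out = r$out, xhat = r$xhat, invstd = r$invstd,
                    gamma = gamma, xd = as.integer(dim(x)),
                    training = training),
       rm = r$rm, rv = r$rv)
}

bnrelu_bwd <- function(dy, cache) {
  cc <- cache
  r <- .bnrelu_bwd_cpp(dy, cc$out, cc$xhat, cc$xd, cc$gamma, cc$invstd,
                       cc$training)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

## ---- activations ----------------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- transposed convolution, kernel 2, stride 2 ---------------------------

# Exact side-doubling upsampler; kernel footprints do not overlap.
tconv2_fwd <- function(x, w, bias = NULL) {
  y <- .tconv2_fwd_cpp(x, as.integer(dim(x)), w, as.integer(dim(w)),
                       if (is.null(bias)) numeric(0) else bias)
  list(out = y, cache = list(x = x, w = w, has_bias = !is.null(bias)))
}

tconv2_bwd <- function(dy, cache) {
  cc <- cache
  .tconv2_bwd_cpp(dy, cc$x, as.integer(dim(cc$x)), cc$w,
                  as.integer(dim(cc$w)), cc$has_bias)
}

## ---- average pooling, kernel = stride = k ---------------------------------

avgpool_fwd <- function(x, k) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (H %% k != 0L || W %% k != 0L)
    stop("avgpool: spatial side ", H, "x", W, " not divisible by kernel ", k)
  Hq <- H %/% k; Wq <- W %/% k
  xr <- x; dim(xr) <- c(N, k, Hq, k, Wq, C)
  xr <- aperm(xr, c(2, 4, 1, 3, 5, 6))
  dim(xr) <- c(k * k, N * Hq * Wq * C)
  y <- array(colMeans(xr), c(N, Hq, Wq, C))
  list(out = y, cache = list(d = d, k = k))
}

avgpool_bwd <- function(dy, cache) {
  d <- cache$d; k <- cache$k
  N <- d[1]; Hq <- d[2] %/% k; Wq <- d[3] %/% k; C <- d[4]
  dxa <- array(rep(as.vector(dy) / (k * k), each = k * k),
               c(k, k, N, Hq, Wq, C))
  dxa <- aperm(dxa, c(3, 1, 4, 2, 5, 6))
  dim(dxa) <- d
  dxa
}

## ---- 2x2 max pooling, stride 2 --------------------------------------------

maxpool2_fwd <- function(x) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Hq <- H %/% 2L; Wq <- W %/% 2L
  xr <- x; dim(xr) <- c(N, 2L, Hq, 2L, Wq, C)
  cand <- list(xr[, 1, , 1, , , drop = FALSE], xr[, 2, , 1, , , drop = FALSE],
               xr[, 1, , 2, , , drop = FALSE], xr[, 2, , 2, , , drop = FALSE])
  cand <- lapply(cand, function(z) array(z, c(N, Hq, Wq, C)))
  y <- cand[[1]]; amax <- array(1L, c(N, Hq, Wq, C))
  for (j in 2:4) {
    upd <- cand[[j]] > y
    y[upd] <- cand[[j]][upd]
    amax[upd] <- j
  }
  list(out = y, cache = list(amax = amax, d = d))
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$d; N <- d[1]; Hq <- d[2] %/% 2L; Wq <- d[3] %/% 2L; C <- d[4]
  dxr <- array(0, c(N, 2L, Hq, 2L, Wq, C))
  sel <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (j in 1:4) {
    m <- dy * (cache$amax == j)
    dxr[, sel[[j]][1], , sel[[j]][2], , ] <-
      dxr[, sel[[j]][1], , sel[[j]][2], , ] + m
  }
  dim(dxr) <- d
  dxr
}

## ---- dense (fully connected) ----------------------------------------------

linear_fwd <- function(x, w, bias = NULL) {
  y <- x %*% w
  if (!is.null(bias)) y <- y + rep(bias, each = nrow(x))
  list(out = y, cache = list(x = x, w = w, has_bias = !is.null(bias)))
}

linear_bwd <- function(dy, cache) {
  list(dx = dy %*% t(cache$w),
       dw = crossprod(cache$x, dy),
       db = if (cache$has_bias) colSums(dy) else NULL)
}

## ---- layer normalization (per row over the embedding dim) -----------------

ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  D <- ncol(x); n <- nrow(x)
  mu <- rowMeans(x)
  v <- rowMeans(x * x) - mu * mu
  invstd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- (x - mu) * invstd
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma))
}

ln_bwd <- function(dy, cache) {
  cc <- cache
  n <- nrow(dy); D <- ncol(dy)
  dgamma <- colSums(dy * cc$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(cc$gamma, each = n)
  s1 <- rowSums(dxhat) / D
  s2 <- rowSums(dxhat * cc$xhat) / D
  dx <- (dxhat - s1 - cc$xhat * s2) * cc$invstd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- softmax --------------------------------------------------------------

softmax_rows <- function(x) {
  m <- x - apply(x, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# gradient of rows-softmax given output y and upstream dy
softmax_rows_bwd <- function(dy, y) (dy - rowSums(dy * y)) * y

## ---- parameter initializers -----------------------------------------------

he_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

he_dw <- function(kh, kw, c) {
  array(stats::rnorm(kh * kw * c, sd = sqrt(2 / (kh * kw))), c(kh, kw, c))
}

glorot_mat <- function(din, dout) {
  matrix(stats::rnorm(din * dout, sd = sqrt(2 / (din + dout))), din, dout)
}
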