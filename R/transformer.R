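# Transformer-based genotype classifier head.
#
# The deepest encoder map (side input/16) is split into patch_grid^2
# non-overlapping patches; each patch is flattened into a token sequence
# (one token per pixel, embedding = channel vector) and passed through a
# shared-weight transformer block (pre-norm multi-head attention + residual,
# then a position-wise feed-forward MLP + residual). The processed patches
# are reassembled, average-pooled, flattened, and mapped by a two-layer MLP
# to two logits followed by a softmax over (wild, mutant).

init_classifier <- function(cfg) {
  D <- cfg$stage_channels[5L]
  side <- cfg$input_size %/% 16L
  pooled <- side %/% cfg$pool_kernel
  P <- pooled * pooled * D
  hid_ffn <- cfg$ffn_mult * D
  list(
    ln1 = list(gamma = rep(1, D), beta = numeric(D)),
    att = list(W_q = glorot_mat(D, D), b_q = numeric(D),
               W_k = glorot_mat(D, D), b_k = numeric(D),
               W_v = glorot_mat(D, D), b_v = numeric(D),
               W_o = glorot_mat(D, D), b_o = numeric(D)),
    ln2 = list(gamma = rep(1, D), beta = numeric(D)),
    ffn = list(W1 = glorot_mat(D, hid_ffn), b1 = numeric(hid_ffn),
               W2 = glorot_mat(hid_ffn, D), b2 = numeric(D)),
    mlp = list(W1 = glorot_mat(P, cfg$mlp_hidden), b1 = numeric(cfg$mlp_hidden),
               W2 = glorot_mat(cfg$mlp_hidden, 2L), b2 = numeric(2L))
  )
}

## ---- attention ------------------------------------------------------------

#' Scaled dot-product self-attention
#'
#' Computes \code{Q = X W_q}, \code{K = X W_k}, \code{V = X W_v} and returns
#' \code{softmax(Q K' / sqrt(d)) V}, where \code{d} is the key dimension
#' (\code{ncol(W_k)}). The row-stochastic attention matrix is attached as
#' attribute \code{"attention"}.
#'
#' @param X token matrix (n_tokens x embed_dim).
#' @param W_q,W_k,W_v projection matrices (embed_dim x d).
#' @return matrix (n_tokens x d) with attribute \code{"attention"}.
#' @export
self_attention <- function(X, W_q, W_k, W_v) {
  if (ncol(X) != nrow(W_q) || ncol(X) != nrow(W_k) || ncol(X) != nrow(W_v))
    stop("dimension mismatch between tokens and projections")
  d <- ncol(W_k)
  Q <- X %*% W_q; K <- X %*% W_k; V <- X %*% W_v
  A <- softmax_rows(Q %*% t(K) / sqrt(d))
  out <- A %*% V
  attr(out, "attention") <- A
  out
}

#' Multi-head attention
#'
#' Splits the embedding into \code{h} per-head column blocks, runs
#' [self_attention()] independently per head, concatenates the head outputs
#' and projects them with \code{W_o}.
#'
#' @param X token matrix (n_tokens x embed_dim).
#' @param params list with \code{W_q}, \code{W_k}, \code{W_v}, \code{W_o},
#'   each (embed_dim x embed_dim); head blocks are consecutive columns.
#' @param h number of heads; must divide the embedding dimension.
#' @return matrix of the same shape as \code{X}.
#' @export
multi_head_attention <- function(X, params, h) {
  D <- ncol(X)
  if (D %% h != 0L) stop("embed_dim ", D, " not divisible by ", h, " heads")
  d <- D %/% h
  heads <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * d + 1L):(i * d)
    heads[[i]] <- self_attention(X, params$W_q[, cols, drop = FALSE],
                                 params$W_k[, cols, drop = FALSE],
                                 params$W_v[, cols, drop = FALSE])
  }
  do.call(cbind, heads) %*% params$W_o
}

# batched-internal multi-head attention with biases and cache
mha_fwd <- function(X, p, h) {
  D <- ncol(X); d <- D %/% h
  n <- nrow(X)
  Q <- X %*% p$W_q + rep(p$b_q, each = n)
  K <- X %*% p$W_k + rep(p$b_k, each = n)
  V <- X %*% p$W_v + rep(p$b_v, each = n)
  O <- matrix(0, n, D)
  As <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * d + 1L):(i * d)
    A <- softmax_rows(Q[, cols, drop = FALSE] %*%
                        t(K[, cols, drop = FALSE]) / sqrt(d))
    O[, cols] <- A %*% V[, cols, drop = FALSE]
    As[[i]] <- A
  }
  out <- O %*% p$W_o + rep(p$b_o, each = n)
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, O = O, As = As,
                               h = h, d = d))
}

mha_bwd <- function(dout, p, cache) {
  cc <- cache; h <- cc$h; d <- cc$d
  n <- nrow(dout); D <- ncol(dout)
  dW_o <- crossprod(cc$O, dout)
  db_o <- colSums(dout)
  dO <- dout %*% t(p$W_o)
  dQ <- matrix(0, n, D); dK <- matrix(0, n, D); dV <- matrix(0, n, D)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * d + 1L):(i * d)
    A <- cc$As[[i]]
    dOi <- dO[, cols, drop = FALSE]
    Vi <- cc$V[, cols, drop = FALSE]
    dA <- dOi %*% t(Vi)
    dV[, cols] <- crossprod(A, dOi)
    dS <- softmax_rows_bwd(dA, A) / sqrt(d)
    dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE])
  }
  dX <- dQ %*% t(p$W_q) + dK %*% t(p$W_k) + dV %*% t(p$W_v)
  list(dx = dX,
       grads = list(W_q = crossprod(cc$X, dQ), b_q = colSums(dQ),
                    W_k = crossprod(cc$X, dK), b_k = colSums(dK),
                    W_v = crossprod(cc$X, dV), b_v = colSums(dV),
                    W_o = dW_o, b_o = db_o))
}

## ---- transformer block ----------------------------------------------------

tblock_fwd <- function(X, p, h) {
  f_ln1 <- ln_fwd(X, p$ln1$gamma, p$ln1$beta)
  f_mha <- mha_fwd(f_ln1$out, p$att, h)
  X1 <- X + f_mha$out
  f_ln2 <- ln_fwd(X1, p$ln2$gamma, p$ln2$beta)
  f_l1 <- linear_fwd(f_ln2$out, p$ffn$W1, p$ffn$b1)
  f_r <- relu_fwd(f_l1$out)
  f_l2 <- linear_fwd(f_r$out, p$ffn$W2, p$ffn$b2)
  list(out = X1 + f_l2$out,
       cache = list(ln1 = f_ln1$cache, mha = f_mha$cache, ln2 = f_ln2$cache,
                    l1 = f_l1$cache, r = f_r$cache, l2 = f_l2$cache))
}

tblock_bwd <- function(dy, p, cache) {
  b_l2 <- linear_bwd(dy, cache$l2)
  d_r <- relu_bwd(b_l2$dx, cache$r)
  b_l1 <- linear_bwd(d_r, cache$l1)
  b_ln2 <- ln_bwd(b_l1$dx, cache$ln2)
  dX1 <- dy + b_ln2$dx
  b_mha <- mha_bwd(dX1, p$att, cache$mha)
  b_ln1 <- ln_bwd(b_mha$dx, cache$ln1)
  dX <- dX1 + b_ln1$dx
  list(dx = dX,
       grads = list(ln1 = list(gamma = b_ln1$dgamma, beta = b_ln1$dbeta),
                    att = b_mha$grads,
                    ln2 = list(gamma = b_ln2$dgamma, beta = b_ln2$dbeta),
                    ffn = list(W1 = b_l1$dw, b1 = b_l1$db,
                               W2 = b_l2$dw, b2 = b_l2$db)))
}

#' Transformer block forward pass
#'
#' Pre-norm arrangement: layer norm, multi-head attention and residual, then
#' layer norm, position-wise feed-forward network and residual. Shape
#' preserving.
#'
#' @param X token matrix (n_tokens x embed_dim).
#' @param params block parameter list with components \code{ln1}, \code{att},
#'   \code{ln2}, \code{ffn} (see [transformer_params()]).
#' @param h number of attention heads.
#' @return matrix of the same shape as \code{X}.
#' @export
transformer_block_forward <- function(X, params, h) {
  if (ncol(X) %% h != 0L) stop("embed_dim not divisible by heads")
  tblock_fwd(X, params, h)$out
}

#' Create transformer block parameters
#'
#' @param embed_dim token embedding dimension.
#' @param num_heads attention heads (must divide \code{embed_dim}).
#' @param ffn_mult feed-forward expansion factor.
#' @return a parameter list for [transformer_block_forward()].
#' @export
transformer_params <- function(embed_dim, num_heads = 4L, ffn_mult = 4L) {
  if (embed_dim %% num_heads != 0L) stop("embed_dim not divisible by heads")
  hid <- ffn_mult * embed_dim
  list(ln1 = list(gamma = rep(1, embed_dim), beta = numeric(embed_dim)),
       att = list(W_q = glorot_mat(embed_dim, embed_dim), b_q = numeric(embed_dim),
                  W_k = glorot_mat(embed_dim, embed_dim), b_k = numeric(embed_dim),
                  W_v = glorot_mat(embed_dim, embed_dim), b_v = numeric(embed_dim),
                  W_o = glorot_mat(embed_dim, embed_dim), b_o = numeric(embed_dim)),
       ln2 = list(gamma = rep(1, embed_dim), beta = numeric(embed_dim)),
       ffn = list(W1 = glorot_mat(embed_dim, hid), b1 = numeric(hid),
                  W2 = glorot_mat(hid, embed_dim), b2 = numeric(embed_dim)))
}

## ---- patch tokenization ---------------------------------------------------

#' Split a feature map into per-patch token sequences
#'
#' Partitions a square (side x side x channels) map into
#' \code{patch_grid^2} non-overlapping square patches and flattens each into
#' a token sequence: one token per pixel (column-major within the patch),
#' embedding = the channel vector. A 24x24 map with \code{patch_grid = 4}
#' yields 16 sequences of 36 tokens.
#'
#' @param f array (side x side x channels).
#' @param patch_grid patches per axis; must divide the side.
#' @return list of \code{patch_grid^2} token matrices, patch row index
#'   varying fastest.
#' @seealso [untokenize_patches()]
#' @export
tokenize_patches <- function(f, patch_grid) {
  d <- dim(f)
  if (length(d) != 3L || d[1] != d[2]) stop("f must be square (side x side x C)")
  side <- d[1]
  if (side %% patch_grid != 0L)
    stop("side ", side, " not divisible by patch_grid ", patch_grid)
  sp <- side %/% patch_grid
  seqs <- vector("list", patch_grid^2)
  k <- 0L
  for (gj in seq_len(patch_grid)) for (gi in seq_len(patch_grid)) {
    k <- k + 1L
    ri <- ((gi - 1L) * sp + 1L):(gi * sp)
    ci <- ((gj - 1L) * sp + 1L):(gj * sp)
    seqs[[k]] <- matrix(f[ri, ci, , drop = FALSE], sp * sp, d[3])
  }
  seqs
}

#' Reassemble token sequences into a feature map
#'
#' Exact inverse of [tokenize_patches()].
#'
#' @param seqs list of token matrices from [tokenize_patches()].
#' @param side spatial side of the reassembled map.
#' @param patch_grid patches per axis.
#' @return array (side x side x channels).
#' @export
untokenize_patches <- function(seqs, side, patch_grid) {
  sp <- side %/% patch_grid
  D <- ncol(seqs[[1]])
  f <- array(0, c(side, side, D))
  k <- 0L
  for (gj in seq_len(patch_grid)) for (gi in seq_len(patch_grid)) {
    k <- k + 1L
    ri <- ((gi - 1L) * sp + 1L):(gi * sp)
    ci <- ((gj - 1L) * sp + 1L):(gj * sp)
    f[ri, ci, ] <- array(seqs[[k]], c(sp, sp, D))
  }
  f
}

## ---- full classifier head -------------------------------------------------

# x: (N, side, side, C) deepest feature maps -> list(q = (N,2) probabilities)
classifier_fwd_b <- function(x, p, cfg) {
  d <- dim(x); N <- d[1]; side <- d[2]; C <- d[4]
  g <- cfg$patch_grid; sp <- side %/% g
  Tn <- sp * sp
  y <- array(0, d)
  caches <- vector("list", N * g * g)
  k <- 0L
  for (n in seq_len(N)) {
    for (gj in seq_len(g)) for (gi in seq_len(g)) {
      k <- k + 1L
      ri <- ((gi - 1L) * sp + 1L):(gi * sp)
      ci <- ((gj - 1L) * sp + 1L):(gj * sp)
      X <- matrix(x[n, ri, ci, , drop = FALSE], Tn, C)
      fb <- tblock_fwd(X, p, cfg$num_heads)
      y[n, ri, ci, ] <- array(fb$out, c(1L, sp, sp, C))
      caches[[k]] <- fb$cache
    }
  }
  f_pool <- avgpool_fwd(y, cfg$pool_kernel)
  pooled_dim <- dim(f_pool$out)
  flat <- matrix(f_pool$out, N, prod(pooled_dim[2:4]))
  f_m1 <- linear_fwd(flat, p$mlp$W1, p$mlp$b1)
  f_r <- relu_fwd(f_m1$out)
  f_m2 <- linear_fwd(f_r$out, p$mlp$W2, p$mlp$b2)
  q <- softmax_rows(f_m2$out)
  list(q = q, logits = f_m2$out,
       cache = list(tb = caches, pool = f_pool$cache, m1 = f_m1$cache,
                    r = f_r$cache, m2 = f_m2$cache, d = d, g = g, sp = sp))
}

# dlogits: gradient w.r.t. the two logits (N,2)
classifier_bwd_b <- function(dlogits, p, cache, cfg) {
  cc <- cache
  N <- cc$d[1]; side <- cc$d[2]; C <- cc$d[4]
  g <- cc$g; sp <- cc$sp; Tn <- sp * sp
  b_m2 <- linear_bwd(dlogits, cc$m2)
  d_r <- relu_bwd(b_m2$dx, cc$r)
  b_m1 <- linear_bwd(d_r, cc$m1)
  dpool_flat <- b_m1$dx
  pd <- c(N, side %/% cfg$pool_kernel, side %/% cfg$pool_kernel, C)
  dy <- avgpool_bwd(array(dpool_flat, pd), cc$pool)
  dx <- array(0, cc$d)
  gsum <- NULL
  k <- 0L
  for (n in seq_len(N)) {
    for (gj in seq_len(g)) for (gi in seq_len(g)) {
      k <- k + 1L
      ri <- ((gi - 1L) * sp + 1L):(gi * sp)
      ci <- ((gj - 1L) * sp + 1L):(gj * sp)
      dY <- matrix(dy[n, ri, ci, , drop = FALSE], Tn, C)
      bb <- tblock_bwd(dY, p, cc$tb[[k]])
      dx[n, ri, ci, ] <- array(bb$dx, c(1L, sp, sp, C))
      gsum <- if (is.null(gsum)) bb$grads else add_grads(gsum, bb$grads)
    }
  }
  gsum$mlp <- list(W1 = b_m1$dw, b1 = b_m1$db, W2 = b_m2$dw, b2 = b_m2$db)
  list(dx = dx, grads = gsum)
}

# element-wise sum of two identically shaped nested gradient lists
add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

#' Genotype probabilities from the deepest feature map
#'
#' Tokenizes the map into patches, applies the shared transformer block,
#' reassembles, average-pools, and maps through the MLP head and softmax.
#'
#' @param f array (side x side x channels) at the deepest level.
#' @param model an [mtsa_net()] object.
#' @return named numeric vector \code{c(wild = , mutant = )} summing to 1.
#' @export
classify <- function(f, model) {
  stopifnot(inherits(model, "mtsa_net"))
  cfg <- model$config
  x <- array(f, c(1L, dim(f)))
  out <- classifier_fwd_b(x, model$params$cls, cfg)
  q <- out$q[1, ]
  names(q) <- c("wild", "mutant")
  q
}
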