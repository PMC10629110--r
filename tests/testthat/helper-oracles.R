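# Brute-force oracles, written independently of the package internals:
# explicit nested loops, no im2col, no vectorized shortcuts.

# dense 2-D convolution, zero padding, stride 1; x: (H,W,Cin), w: (kh,kw,Cin,Cout)
oracle_conv2d <- function(x, w, bias = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  y <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- if (is.null(bias)) 0 else bias[co]
    for (a in seq_len(kh)) for (b in seq_len(kw)) for (ci in seq_len(cin)) {
      ii <- i + a - 1 - ph; jj <- j + b - 1 - pw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, ci] * w[a, b, ci, co]
    }
    y[i, j, co] <- acc
  }
  y
}

# depth-wise convolution; w: (kh,kw,C)
oracle_dwconv <- function(x, w, bias = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  y <- array(0, dim(x))
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- if (is.null(bias)) 0 else bias[c]
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      ii <- i + a - 1 - ph; jj <- j + b - 1 - pw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, c] * w[a, b, c]
    }
    y[i, j, c] <- acc
  }
  y
}

# MSA layer by direct composition of the loop-based convolutions
oracle_msa_layer <- function(f, params) {
  s <- oracle_conv2d(f, params$local$w, params$local$b)
  shared <- oracle_dwconv(f, params$dw$w, params$dw$b)
  for (br in params$br) {
    v <- oracle_dwconv(shared, br$v$w, br$v$b)
    h <- oracle_dwconv(v, br$h$w, br$h$b)
    s <- s + h
  }
  C <- dim(f)[3]
  att <- array(0, dim(f))
  for (i in seq_len(dim(f)[1])) for (j in seq_len(dim(f)[2]))
    att[i, j, ] <- as.vector(s[i, j, ] %*% params$mix$w) + params$mix$b
  att * f
}

# scaled dot-product attention with explicit loops
oracle_attention <- function(X, Wq, Wk, Wv) {
  n <- nrow(X); d <- ncol(Wk)
  Q <- matrix(0, n, ncol(Wq)); K <- matrix(0, n, d); V <- matrix(0, n, ncol(Wv))
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(Wq))) Q[i, j] <- sum(X[i, ] * Wq[, j])
    for (j in seq_len(d)) K[i, j] <- sum(X[i, ] * Wk[, j])
    for (j in seq_len(ncol(Wv))) V[i, j] <- sum(X[i, ] * Wv[, j])
  }
  out <- matrix(0, n, ncol(Wv))
  for (i in seq_len(n)) {
    scores <- numeric(n)
    for (j in seq_len(n)) scores[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    e <- exp(scores - max(scores))
    a <- e / sum(e)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

# all-pairs HD95 oracle with hand-rolled linear-interpolation percentile
oracle_hd95 <- function(pred, true, spacing = c(1, 1)) {
  bnd <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (m[i, j] == 1) {
        nb <- c(if (i > 1) m[i - 1, j] else 0, if (i < nr) m[i + 1, j] else 0,
                if (j > 1) m[i, j - 1] else 0, if (j < nc) m[i, j + 1] else 0)
        if (any(nb == 0)) out[i, j] <- TRUE
      }
    }
    out
  }
  pct95 <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n == 1) return(v)
    h <- (n - 1) * 0.95 + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[lo + 1] - v[lo])
  }
  bp <- which(bnd(pred), arr.ind = TRUE)
  bt <- which(bnd(true), arr.ind = TRUE)
  d_pt <- numeric(nrow(bp))
  for (i in seq_len(nrow(bp))) {
    best <- Inf
    for (j in seq_len(nrow(bt))) {
      d <- sqrt(((bp[i, 1] - bt[j, 1]) * spacing[1])^2 +
                  ((bp[i, 2] - bt[j, 2]) * spacing[2])^2)
      if (d < best) best <- d
    }
    d_pt[i] <- best
  }
  d_tp <- numeric(nrow(bt))
  for (i in seq_len(nrow(bt))) {
    best <- Inf
    for (j in seq_len(nrow(bp))) {
      d <- sqrt(((bt[i, 1] - bp[j, 1]) * spacing[1])^2 +
                  ((bt[i, 2] - bp[j, 2]) * spacing[2])^2)
      if (d < best) best <- d
    }
    d_tp[i] <- best
  }
  max(pct95(d_pt), pct95(d_tp))
}

# pixel confusion counts with an explicit loop
oracle_pixel_counts <- function(pred, true) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] == 1 && true[i, j] == 1) tp <- tp + 1
    else if (pred[i, j] == 1) fp <- fp + 1
    else if (true[i, j] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# random binary mask with a blob-ish structure
random_mask <- function(nr, nc, p = 0.3) {
  m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
  m
}

# maximum relative deviation, normalized by the largest magnitude present
max_rel_dev <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(a)), max(abs(b)))
}

tiny_config <- function(...) {
  mtsa_config(input_size = 32L, stage_channels = c(2L, 2L, 4L, 4L, 4L),
              num_heads = 2L, patch_grid = 2L, pool_kernel = 2L,
              mlp_hidden = 8L, ffn_mult = 2L, batch_size = 4L, ...)
}

tiny_phantom <- function(...) {
  args <- list(image_size = 32L, lesion_radius = c(3L, 6L),
               slices_per_patient = c(2L, 4L))
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_params, args)
}
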