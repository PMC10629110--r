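# Model assembly: parameter initialization, the joint forward/backward pass
# over both heads, the Adam optimizer, and weight checkpointing.
#
# All parameters live in one nested named list; leaf arrays are addressed by
# dot-joined paths (e.g. "enc.s1.block.conv.w", "cls.att.W_q",
# "dec.u1.tconv.w", "sigma.s"). Batch-norm running statistics (leaves "rm",
# "rv") are buffers, not trainable parameters.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Initialize a multi-task network
#'
#' Builds the shared MSA encoder, transformer classifier head, segmentation
#' decoder and the two uncertainty parameters (sigma, stored as
#' log-variances, initialized so sigma = 1). Weight initialization is
#' seeded and reproducible.
#'
#' @param config an [mtsa_config()].
#' @param seed integer; defaults to \code{config$seed}.
#' @return an object of class \code{mtsa_net}.
#' @export
mtsa_net <- function(config = mtsa_config(), seed = config$seed) {
  validate_config(config)
  params <- with_seed(seed, {
    enc <- init_encoder(config)
    names(enc) <- paste0("s", 1:5)
    for (l in 1:5) names(enc[[l]]$block$msa$br) <-
        paste0("b", seq_along(enc[[l]]$block$msa$br))
    dec <- init_decoder(config)
    names(dec$ups) <- paste0("u", 1:4)
    list(enc = enc,
         cls = init_classifier(config),
         dec = dec,
         sigma = list(s = c(gtv = 0, egfr = 0)))
  })
  structure(list(config = config, params = params, trained = FALSE,
                 history = NULL, best_epoch = NA_integer_),
            class = "mtsa_net")
}

#' Current uncertainty parameters of a model
#' @param model an \code{mtsa_net} object.
#' @return named vector \code{c(sigma_gtv = , sigma_egfr = )}.
#' @export
sigmas <- function(model) {
  s <- model$params$sigma$s
  c(sigma_gtv = exp(s[["gtv"]] / 2), sigma_egfr = exp(s[["egfr"]] / 2))
}

## ---- parameter flattening -------------------------------------------------

flatten_params <- function(x, prefix = character(0), out = list()) {
  if (is.null(x)) return(out)
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- flatten_params(x[[i]], c(prefix, key), out)
    }
    out
  } else {
    out[[paste(prefix, collapse = ".")]] <- x
    out
  }
}

get_path <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

set_path <- function(x, path, v) {
  if (length(path) == 1L) {
    x[[path]] <- v
    return(x)
  }
  x[[path[1L]]] <- set_path(x[[path[1L]]], path[-1L], v)
  x
}

#' Number of trainable parameters
#'
#' A pure function of the configuration (batch-norm running statistics are
#' excluded).
#'
#' @param model an \code{mtsa_net} object.
#' @return integer count.
#' @export
n_params <- function(model) {
  fl <- flatten_params(model$params)
  keep <- !grepl("\\.(rm|rv)$", names(fl))
  sum(vapply(fl[keep], length, integer(1)))
}

## ---- joint forward/backward -----------------------------------------------

# xb: (N,H,W,1); yb: (N,H,W); lb: 0/1 labels. task_scale multiplies the two
# task losses (diagnostic hook; both 1 in normal training).
model_grad_b <- function(params, cfg, xb, yb, lb, training = TRUE,
                         task_scale = c(gtv = 1, egfr = 1)) {
  enc <- encoder_fwd_b(xb, params$enc, cfg, training)
  dec <- decoder_fwd_b(enc$feats, params$dec, training, cfg$bn_momentum)
  cls <- classifier_fwd_b(enc$feats[[5L]], params$cls, cfg)
  sg <- seg_loss_grad_b(dec$prob, yb, cfg)
  ce <- ce_loss_grad_b(cls$q, lb, cfg$prob_floor)
  l_gtv <- task_scale[[1]] * sg$l_gtv
  l_egfr <- task_scale[[2]] * ce$l
  jw <- joint_weights(l_gtv, l_egfr, params$sigma$s, cfg$weighting_mode)
  dz_seg <- (jw$w[1] * task_scale[[1]]) * sg$dp * dec$prob * (1 - dec$prob)
  db_dec <- decoder_bwd_b(dz_seg, params$dec, dec$cache)
  dlogits <- (jw$w[2] * task_scale[[2]]) * ce$dlogits
  db_cls <- classifier_bwd_b(dlogits, params$cls, cls$cache, cfg)
  dfeats <- db_dec$dfeats
  dfeats[[5L]] <- dfeats[[5L]] + db_cls$dx
  db_enc <- encoder_bwd_b(dfeats, params$enc, cfg, enc$caches)
  g_enc <- db_enc$grads
  names(g_enc) <- paste0("s", 1:5)
  for (l in 1:5) names(g_enc[[l]]$block$msa$br) <-
      paste0("b", seq_along(g_enc[[l]]$block$msa$br))
  g_dec <- db_dec$grads
  names(g_dec$ups) <- paste0("u", 1:4)
  list(loss = list(l_dice = sg$l_dice, l_focal = sg$l_focal, l_gtv = l_gtv,
                   l_egfr = l_egfr, l_joint = jw$joint),
       grads = list(enc = g_enc, cls = db_cls$grads, dec = g_dec,
                    sigma = list(s = jw$ds)),
       bn = list(enc = enc$bn_stats, dec = dec$bn_stats))
}

# classifier-only pass (single-task ablation: no decoder branch, plain
# cross-entropy objective)
model_grad_cls_b <- function(params, cfg, xb, lb, training = TRUE) {
  enc <- encoder_fwd_b(xb, params$enc, cfg, training)
  cls <- classifier_fwd_b(enc$feats[[5L]], params$cls, cfg)
  ce <- ce_loss_grad_b(cls$q, lb, cfg$prob_floor)
  db_cls <- classifier_bwd_b(ce$dlogits, params$cls, cls$cache, cfg)
  dfeats <- vector("list", 5L)
  dfeats[[5L]] <- db_cls$dx
  db_enc <- encoder_bwd_b(dfeats, params$enc, cfg, enc$caches)
  g_enc <- db_enc$grads
  names(g_enc) <- paste0("s", 1:5)
  for (l in 1:5) names(g_enc[[l]]$block$msa$br) <-
      paste0("b", seq_along(g_enc[[l]]$block$msa$br))
  list(loss = list(l_dice = NA_real_, l_focal = NA_real_, l_gtv = NA_real_,
                   l_egfr = ce$l, l_joint = ce$l),
       grads = list(enc = g_enc, cls = db_cls$grads),
       bn = list(enc = enc$bn_stats, dec = NULL))
}

# losses only, no gradient bookkeeping (validation)
model_loss_b <- function(params, cfg, xb, yb, lb) {
  enc <- encoder_fwd_b(xb, params$enc, cfg, FALSE)
  dec <- decoder_fwd_b(enc$feats, params$dec, FALSE)
  cls <- classifier_fwd_b(enc$feats[[5L]], params$cls, cfg)
  sg <- seg_loss_grad_b(dec$prob, yb, cfg)
  ce <- ce_loss_grad_b(cls$q, lb, cfg$prob_floor)
  jw <- joint_weights(sg$l_gtv, ce$l, params$sigma$s, cfg$weighting_mode)
  list(l_dice = sg$l_dice, l_focal = sg$l_focal, l_gtv = sg$l_gtv,
       l_egfr = ce$l, l_joint = jw$joint)
}

# inference forward: probabilities for a batch of slices
model_predict_b <- function(params, cfg, xb) {
  enc <- encoder_fwd_b(xb, params$enc, cfg, FALSE)
  dec <- decoder_fwd_b(enc$feats, params$dec, FALSE)
  cls <- classifier_fwd_b(enc$feats[[5L]], params$cls, cfg)
  list(prob = dec$prob, q = cls$q)
}

# write freshly computed BN running statistics back into the parameter tree
apply_bn_stats <- function(params, bn) {
  for (l in 1:5) {
    params$enc[[l]]$block$bn$rm <- bn$enc[[l]]$rm
    params$enc[[l]]$block$bn$rv <- bn$enc[[l]]$rv
  }
  if (!is.null(bn$dec)) {
    for (i in 1:4) {
      params$dec$ups[[i]]$bn$rm <- bn$dec[[i]]$rm
      params$dec$ups[[i]]$bn$rv <- bn$dec[[i]]$rv
    }
  }
  params
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function() list(m = list(), v = list(), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  g <- flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(g)) {
    gi <- g[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gi * 0
      state$v[[nm]] <- gi * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gi
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gi * gi
    upd <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    params <- set_path(params, path, get_path(params, path) - upd)
  }
  list(params = params, state = state)
}

## ---- checkpoints ----------------------------------------------------------

#' Save model weights
#'
#' Writes the full parameter tree (including batch-norm running statistics
#' and the uncertainty parameters) together with the configuration. Leaf
#' names follow the stable dot-path scheme, e.g. \code{enc.s1.block.conv.w}.
#'
#' @param model an \code{mtsa_net} object.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
save_weights <- function(model, path) {
  saveRDS(list(format = "mtsanet-weights-1", config = unclass(model$config),
               params = model$params, trained = model$trained,
               best_epoch = model$best_epoch),
          path)
  invisible(path)
}

#' Load model weights
#' @param path file written by [save_weights()].
#' @return an \code{mtsa_net} object.
#' @export
load_weights <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "mtsanet-weights-1"))
    stop("not a recognized weights file")
  cfg <- do.call(mtsa_config, x$config[names(formals(mtsa_config))])
  structure(list(config = cfg, params = x$params, trained = x$trained,
                 history = NULL, best_epoch = x$best_epoch),
            class = "mtsa_net")
}

#' @export
print.mtsa_net <- function(x, ...) {
  cat("Multi-task segmentation/genotyping network\n")
  print(x$config)
  cat(sprintf("  %s, %d trainable parameters\n",
              if (x$trained) "trained" else "untrained", n_params(x)))
  s <- sigmas(x)
  cat(sprintf("  sigma_gtv %.3f, sigma_egfr %.3f\n", s[1], s[2]))
  invisible(x)
}
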