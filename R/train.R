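# Training and inference engine.
#
# Optimization follows the published protocol: one Adam optimizer (initial
# learning rate 3e-4) over all network weights and the two log-variance
# uncertainty parameters; slices are shuffled across patients each epoch;
# training stops when the validation joint loss (computed with the current
# sigmas frozen, batch norm in inference mode) has not improved by at least
# min_delta for `patience` consecutive epochs, and the best-validation
# checkpoint is returned.

#' Patient-level train/validation split
#'
#' @param cohort list of [patient_case()] objects.
#' @param n_val number of validation patients.
#' @param seed split seed.
#' @return list with \code{train} and \code{val} patient lists (disjoint).
#' @export
split_cohort <- function(cohort, n_val, seed = 0L) {
  n <- length(cohort)
  if (n_val >= n) stop("n_val (", n_val, ") must be smaller than cohort size (",
                       n, ")")
  idx <- with_seed(seed, sample.int(n, n_val))
  list(train = cohort[-idx], val = cohort[idx])
}

# early-stopping bookkeeping; pure so the rule is testable in isolation.
# state: list(best, best_epoch, wait); returns updated state + flags.
update_best <- function(state, epoch, val_loss, patience, min_delta = 1e-6) {
  improved <- val_loss < state$best - min_delta
  if (improved) {
    state$best <- val_loss
    state$best_epoch <- epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
  }
  state$stop <- state$wait >= patience
  state$improved <- improved
  state
}

#' Fit the multi-task network
#'
#' Trains segmentation and classification jointly on lesion-bearing slices.
#' Slice intensities are z-score normalized per slice. Returns the
#' best-validation checkpoint together with the full per-epoch history
#' (task losses, sigmas, validation loss).
#'
#' @param train,val lists of [patient_case()] objects (patient-disjoint).
#' @param config an [mtsa_config()].
#' @param epochs maximum number of epochs.
#' @param branches \code{"both"} for the full multi-task model or
#'   \code{"classifier_only"} for the single-task ablation without the
#'   decoder branch.
#' @param task_scale named multipliers \code{c(gtv=, egfr=)} applied to the
#'   two task losses before weighting (diagnostic hook, both 1 normally).
#' @param verbose print one line per epoch.
#' @return an object of class \code{mtsa_net} with elements \code{history}
#'   (data frame) and \code{best_epoch}.
#' @export
mtsa_fit <- function(train, val, config = mtsa_config(), epochs = 100L,
                     branches = c("both", "classifier_only"),
                     task_scale = c(gtv = 1, egfr = 1), verbose = FALSE) {
  branches <- match.arg(branches)
  validate_config(config)
  if (length(train) == 0 || length(val) == 0)
    stop("train and validation sets must be non-empty")
  model <- mtsa_net(config)
  tr <- cohort_tensors(train)
  va <- cohort_tensors(val)
  n_tr <- dim(tr$x)[1]
  bs <- config$batch_size
  params <- model$params
  opt <- adam_init()
  state <- list(best = Inf, best_epoch = 0L, wait = 0L)
  best_params <- params
  hist <- vector("list", epochs)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n_tr)
      nb <- ceiling(n_tr / bs)
      acc <- c(l_dice = 0, l_focal = 0, l_gtv = 0, l_egfr = 0, l_joint = 0)
      for (b in seq_len(nb)) {
        take <- idx[((b - 1L) * bs + 1L):min(b * bs, n_tr)]
        xb <- tr$x[take, , , , drop = FALSE]
        yb <- tr$y[take, , , drop = FALSE]
        lb <- tr$label[take]
        res <- if (branches == "both") {
          model_grad_b(params, config, xb, yb, lb, training = TRUE,
                       task_scale = task_scale)
        } else {
          model_grad_cls_b(params, config, xb, lb, training = TRUE)
        }
        if (!is.finite(res$loss$l_joint))
          stop("training diverged at epoch ", ep, " (non-finite joint loss)")
        params <- apply_bn_stats(params, res$bn)
        st <- adam_step(params, res$grads, opt, config$learning_rate)
        params <- st$params
        opt <- st$state
        acc <- acc + unlist(res$loss)[names(acc)] / nb
      }
      val_loss <- validation_loss(params, config, va, branches)
      s <- exp(params$sigma$s / 2)
      hist[[ep]] <- data.frame(epoch = ep, t(acc),
                               sigma_gtv = s[["gtv"]], sigma_egfr = s[["egfr"]],
                               val_loss = val_loss)
      state <- update_best(state, ep, val_loss, config$patience,
                           config$min_delta)
      if (state$improved) best_params <- params
      if (verbose)
        message(sprintf(
          "epoch %3d  dice %.4f  focal %.1f  egfr %.4f  joint %.4f  val %.4f%s",
          ep, acc["l_dice"], acc["l_focal"], acc["l_egfr"], acc["l_joint"],
          val_loss, if (state$improved) " *" else ""))
      if (state$stop) break
    }
  })
  model$params <- best_params
  model$trained <- TRUE
  model$branches <- branches
  model$best_epoch <- state$best_epoch
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model
}

# validation joint loss, batched, eval mode, sigmas frozen
validation_loss <- function(params, cfg, va, branches = "both") {
  n <- dim(va$x)[1]
  bs <- cfg$batch_size
  nb <- ceiling(n / bs)
  tot <- 0
  for (b in seq_len(nb)) {
    take <- ((b - 1L) * bs + 1L):min(b * bs, n)
    xb <- va$x[take, , , , drop = FALSE]
    if (branches == "both") {
      l <- model_loss_b(params, cfg, xb, va$y[take, , , drop = FALSE],
                        va$label[take])
    } else {
      enc <- encoder_fwd_b(xb, params$enc, cfg, FALSE)
      cls <- classifier_fwd_b(enc$feats[[5L]], params$cls, cfg)
      l <- list(l_joint = ce_loss_grad_b(cls$q, va$label[take],
                                         cfg$prob_floor)$l)
    }
    tot <- tot + l$l_joint * length(take) / n
  }
  tot
}

#' Predict segmentation and genotype for patients
#'
#' Runs the per-slice forward pass in inference mode (batch-norm running
#' statistics) and aggregates slice evidence into one genotype call per
#' patient: slices ranked by predicted lesion area, upper half averaged,
#' strict 0.5 threshold (see [aggregate_patient()]).
#'
#' @param object a trained \code{mtsa_net}.
#' @param newdata a [patient_case()] or a list of them.
#' @param ... unused.
#' @return for one patient, a list with \code{slices} (list of
#'   [slice_prediction()]) and \code{call} (a \code{patient_call}); for a
#'   cohort, a list of such results.
#' @export
predict.mtsa_net <- function(object, newdata, ...) {
  single <- inherits(newdata, "patient_case")
  cohort <- if (single) list(newdata) else newdata
  cfg <- object$config
  out <- lapply(cohort, function(pat) {
    te <- cohort_tensors(list(pat))
    n <- dim(te$x)[1]
    bs <- cfg$batch_size
    preds <- vector("list", n)
    for (b in seq_len(ceiling(n / bs))) {
      take <- ((b - 1L) * bs + 1L):min(b * bs, n)
      pr <- model_predict_b(object$params, cfg,
                            te$x[take, , , , drop = FALSE])
      for (j in seq_along(take)) {
        i <- take[j]
        preds[[i]] <- slice_prediction(
          seg_prob = matrix(pr$prob[j, , ], dim(te$x)[2], dim(te$x)[3]),
          mutation_prob = pr$q[j, 2L],
          slice_index = te$slice_index[i],
          seg_threshold = cfg$seg_threshold)
      }
    }
    ev <- data.frame(
      slice_index = vapply(preds, `[[`, integer(1), "slice_index"),
      area = vapply(preds, function(p) slice_area(p$seg_mask), integer(1)),
      mutation_prob = vapply(preds, `[[`, numeric(1), "mutation_prob"))
    call <- aggregate_patient(ev, threshold = cfg$class_threshold,
                              patient_id = pat$patient_id)
    list(slices = preds, call = call)
  })
  if (single) out[[1]] else out
}

#' Evaluate a trained model on a cohort
#'
#' Slice-level segmentation metrics (Dice, HD95, pixel precision/recall,
#' averaged over slices) and patient-level classification metrics from the
#' aggregated genotype calls.
#'
#' @param model a trained \code{mtsa_net}.
#' @param cohort list of [patient_case()] objects with ground truth.
#' @param spacing pixel spacing in mm passed to [hd95()].
#' @return an object of class \code{mtsa_eval}: list with \code{seg}
#'   (named means), \code{cls} (named metrics), and \code{per_patient}
#'   (data frame).
#' @export
evaluate_cohort <- function(model, cohort, spacing = c(1, 1)) {
  preds <- predict(model, cohort)
  dice <- c(); hd <- c(); prec <- c(); rec <- c()
  rows <- list()
  for (i in seq_along(cohort)) {
    pat <- cohort[[i]]
    for (j in seq_along(pat$slices)) {
      pm <- preds[[i]]$slices[[j]]$seg_mask
      tm <- pat$slices[[j]]$mask
      dice <- c(dice, dice_score(pm, tm))
      h <- hd95(pm, tm, spacing)
      if (is.null(attr(h, "degenerate"))) hd <- c(hd, h)
      pr <- pixel_precision_recall(pm, tm)
      prec <- c(prec, pr["precision"]); rec <- c(rec, pr["recall"])
    }
    cl <- preds[[i]]$call
    rows[[i]] <- data.frame(patient_id = pat$patient_id,
                            truth = pat$genotype,
                            label = cl$label,
                            mean_prob = cl$mean_prob)
  }
  per_patient <- do.call(rbind, rows)
  structure(list(
    seg = c(dice = mean(dice), hd95 = if (length(hd)) mean(hd) else NA_real_,
            precision = mean(prec), recall = mean(rec)),
    cls = classification_report(per_patient$label, per_patient$truth),
    per_patient = per_patient),
    class = "mtsa_eval")
}

#' @export
print.mtsa_eval <- function(x, ...) {
  cat("Segmentation (slice level):\n")
  cat(sprintf("  Dice %.4f   HD95 %.2f mm   precision %.4f   recall %.4f\n",
              x$seg["dice"], x$seg["hd95"], x$seg["precision"],
              x$seg["recall"]))
  cat("EGFR genotyping (patient level):\n")
  cat(sprintf("  accuracy %.4f   precision %.4f   recall %.4f   F1 %.4f\n",
              x$cls["accuracy"], x$cls["precision"], x$cls["recall"],
              x$cls["f1"]))
  cat(sprintf("  %d patients\n", nrow(x$per_patient)))
  invisible(x)
}

#' @export
summary.mtsa_net <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat(sprintf("  trained %d epochs, best validation loss %.5f at epoch %d\n",
                nrow(object$history), min(object$history$val_loss),
                object$best_epoch))
  }
  invisible(object)
}

#' @export
coef.mtsa_net <- function(object, ...) sigmas(object)

#' Training curves
#'
#' Plots the training losses, the validation joint loss, and the evolution
#' of the two uncertainty parameters.
#'
#' @param x a trained \code{mtsa_net}.
#' @param ... unused.
#' @export
plot.mtsa_net <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  rng <- range(c(h$l_joint, h$val_loss), finite = TRUE)
  plot(h$epoch, h$l_joint, type = "l", col = "steelblue", ylim = rng,
       xlab = "epoch", ylab = "joint loss", main = "loss")
  graphics::lines(h$epoch, h$val_loss, col = "firebrick")
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  rng2 <- range(c(h$sigma_gtv, h$sigma_egfr))
  plot(h$epoch, h$sigma_gtv, type = "l", col = "steelblue", ylim = rng2,
       xlab = "epoch", ylab = expression(sigma), main = "task uncertainty")
  graphics::lines(h$epoch, h$sigma_egfr, col = "firebrick")
  graphics::legend("topright", c(expression(sigma[GTV]),
                                 expression(sigma[EGFR])),
                   lty = 1, col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
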