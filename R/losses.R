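# Training objectives.
#
# Segmentation: Dice loss plus a pixel-summed two-sided focal loss scaled by
# beta (default 1/25000, chosen because the summed focal term is ~25000x the
# Dice term at typical image sizes). Classification: cross-entropy.
# Joint: homoscedastic uncertainty weighting
#   L = L_gtv/(2 sigma_gtv^2) + L_egfr/(2 sigma_egfr^2)
#       + log(sigma_gtv * sigma_egfr),
# with the sigmas learned in log-variance space (s = log sigma^2) for
# positivity; or fixed equal weights 0.5/0.5. Probabilities are floored at
# prob_floor before any logarithm.

check_seg_pair <- function(p, y) {
  if (!identical(dim(p), dim(y)))
    stop("shape mismatch: ", paste(dim(p), collapse = "x"), " vs ",
         paste(dim(y), collapse = "x"))
  if (any(p < 0 | p > 1)) stop("probabilities outside [0,1]")
  if (!all(y %in% c(0, 1))) stop("ground truth must be binary")
}

#' Dice loss
#'
#' \code{1 - 2 sum(p y) / (sum(p + y) + epsilon)}; lies in [0,1] and is 0
#' for a perfect binary prediction (up to epsilon).
#'
#' @param p predicted probabilities in [0,1] (any shape).
#' @param y binary ground truth of the same shape.
#' @param epsilon smoothing constant protecting the denominator.
#' @return scalar loss.
#' @export
dice_loss <- function(p, y, epsilon = 1e-6) {
  check_seg_pair(p, y)
  1 - 2 * sum(p * y) / (sum(p + y) + epsilon)
}

#' Focal loss (pixel-summed, two-sided)
#'
#' \code{-sum_i a_i (1 - pt_i)^gamma log(pt_i)} where \code{pt_i} is the
#' predicted probability of the true class at pixel i and \code{a_i} equals
#' \code{alpha} on foreground pixels, \code{1 - alpha} on background. The sum
#' (rather than mean) over pixels is intentional: it gives the magnitude that
#' the beta scale in [seg_loss()] compensates. Probabilities are floored
#' before the logarithm, so a hard 0 never raises an error.
#'
#' @param p predicted foreground probabilities.
#' @param y binary ground truth of the same shape.
#' @param alpha foreground balance weight in (0,1).
#' @param gamma focusing exponent, >= 0.
#' @param floor probability floor before the logarithm.
#' @return scalar loss >= 0.
#' @export
focal_loss <- function(p, y, alpha = 0.8, gamma = 2, floor = 1e-7) {
  check_seg_pair(p, y)
  pt <- ifelse(y == 1, p, 1 - p)
  pt <- pmin(pmax(pt, floor), 1)
  a <- ifelse(y == 1, alpha, 1 - alpha)
  -sum(a * (1 - pt)^gamma * log(pt))
}

#' Combined segmentation loss
#'
#' \code{l_gtv = l_dice + beta * l_focal}.
#'
#' @param p predicted probabilities; @param y binary ground truth.
#' @param cfg an [mtsa_config()] supplying epsilon, alpha, gamma and beta.
#' @return list with \code{l_gtv}, \code{l_dice}, \code{l_focal}.
#' @export
seg_loss <- function(p, y, cfg = mtsa_config()) {
  l_dice <- dice_loss(p, y, cfg$dice_epsilon)
  l_focal <- focal_loss(p, y, cfg$focal_alpha, cfg$focal_gamma, cfg$prob_floor)
  list(l_gtv = l_dice + cfg$focal_scale_beta * l_focal,
       l_dice = l_dice, l_focal = l_focal)
}

#' Classification cross-entropy
#'
#' \code{-log q[true class]}, averaged over the batch. Predicted
#' probabilities are floored before the logarithm.
#'
#' @param q class probabilities: a length-2 vector (wild, mutant) or an
#'   (n x 2) matrix with rows summing to 1.
#' @param label binary label(s), 1 = mutant.
#' @param floor probability floor.
#' @return scalar loss.
#' @export
ce_loss <- function(q, label, floor = 1e-7) {
  if (is.null(dim(q))) q <- matrix(q, 1L)
  if (length(label) != nrow(q)) stop("one label per probability row required")
  if (any(abs(rowSums(q) - 1) > 1e-6)) stop("probability rows must sum to 1")
  picked <- q[cbind(seq_len(nrow(q)), label + 1L)]
  -mean(log(pmax(picked, floor)))
}

#' Joint multi-task loss
#'
#' Uncertainty mode weights each task by \code{1/(2 sigma^2)} and adds the
#' \code{log(sigma_gtv * sigma_egfr)} penalty; equal mode returns
#' \code{0.5 l_gtv + 0.5 l_egfr}.
#'
#' @param l_gtv,l_egfr task losses.
#' @param sigma_gtv,sigma_egfr positive uncertainty parameters.
#' @param mode \code{"uncertainty"} or \code{"equal"}.
#' @return scalar joint loss.
#' @export
joint_loss <- function(l_gtv, l_egfr, sigma_gtv = 1, sigma_egfr = 1,
                       mode = c("uncertainty", "equal")) {
  mode <- match.arg(mode)
  if (mode == "equal") return(0.5 * l_gtv + 0.5 * l_egfr)
  if (sigma_gtv <= 0 || sigma_egfr <= 0) stop("sigma must be positive")
  l_gtv / (2 * sigma_gtv^2) + l_egfr / (2 * sigma_egfr^2) +
    log(sigma_gtv * sigma_egfr)
}

## ---- batched losses with gradients (training path) ------------------------

# p, y: (N,H,W); returns per-batch means and d(loss)/dp
seg_loss_grad_b <- function(p, y, cfg) {
  d <- dim(p); N <- d[1]
  npix <- prod(d[2:3])
  pm <- matrix(p, N, npix)
  ym <- matrix(y, N, npix)
  num <- 2 * rowSums(pm * ym)
  den <- rowSums(pm + ym) + cfg$dice_epsilon
  l_dice_n <- 1 - num / den
  ddice <- (-2 * ym / den + num / den^2) / N
  a <- cfg$focal_alpha; g <- cfg$focal_gamma; fl <- cfg$prob_floor
  pc <- pmin(pmax(pm, fl), 1 - fl)
  fg <- ym == 1
  lt <- ifelse(fg, log(pc), log(1 - pc))
  omt <- ifelse(fg, 1 - pc, pc)          # 1 - pt
  av <- ifelse(fg, a, 1 - a)
  l_focal_n <- -rowSums(av * omt^g * lt)
  pt <- ifelse(fg, pc, 1 - pc)
  # d[-a (1-pt)^g log pt]/dpt = a g (1-pt)^(g-1) log pt - a (1-pt)^g / pt
  term1 <- if (g > 0) g * omt^(g - 1) * lt else 0
  dfocal_dpt <- av * (term1 - omt^g / pt)
  dfocal <- ifelse(fg, dfocal_dpt, -dfocal_dpt) / N
  l_dice <- mean(l_dice_n)
  l_focal <- mean(l_focal_n)
  dp <- array(ddice + cfg$focal_scale_beta * dfocal, d)
  list(l_gtv = l_dice + cfg$focal_scale_beta * l_focal,
       l_dice = l_dice, l_focal = l_focal, dp = dp)
}

# q: (N,2) softmax output; label: 0/1 vector; returns loss and dlogits
ce_loss_grad_b <- function(q, label, floor = 1e-7) {
  N <- nrow(q)
  picked <- pmax(q[cbind(seq_len(N), label + 1L)], floor)
  onehot <- matrix(0, N, 2L)
  onehot[cbind(seq_len(N), label + 1L)] <- 1
  list(l = -mean(log(picked)), dlogits = (q - onehot) / N)
}

# s = c(s_gtv, s_egfr) log-variances; returns weights, penalty and ds
joint_weights <- function(l_gtv, l_egfr, s, mode) {
  if (mode == "equal") {
    list(w = c(0.5, 0.5), penalty = 0, ds = c(0, 0),
         joint = 0.5 * l_gtv + 0.5 * l_egfr)
  } else {
    w <- unname(exp(-s) / 2)
    penalty <- sum(s) / 2
    joint <- unname(w[1] * l_gtv + w[2] * l_egfr + penalty)
    ds <- unname(c(-w[1] * l_gtv + 0.5, -w[2] * l_egfr + 0.5))
    list(w = w, penalty = penalty, ds = ds, joint = joint)
  }
}
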