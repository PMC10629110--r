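test_that("Dice loss reproduces hand-evaluated cases", {
  y <- matrix(c(1, 0), 1)
  p <- matrix(c(0.5, 0.5), 1)
  # 1 - (2*0.5) / (0.5 + 0.5 + 1) with no smoothing
  expect_equal(dice_loss(p, y, epsilon = 0), 0.5)
  yk <- matrix(0, 6, 6); yk[2:4, 2:4] <- 1
  expect_equal(dice_loss(yk, yk, epsilon = 1e-6), 1 - 18 / (18 + 1e-6))
  expect_lt(dice_loss(yk, yk), 1e-6)
  expect_equal(dice_loss(yk * 0, yk), 1, tolerance = 1e-6)
  expect_error(dice_loss(matrix(2, 2, 2), matrix(1, 2, 2)), "outside")
  expect_error(dice_loss(matrix(.5, 2, 2), matrix(1, 3, 2)), "mismatch")
})

test_that("Dice loss is bounded and monotone in foreground probability", {
  set.seed(21)
  for (rep in 1:20) {
    y <- matrix(rbinom(64, 1, 0.3), 8, 8)
    p <- matrix(runif(64), 8, 8)
    l <- dice_loss(p, y)
    expect_gte(l, 0); expect_lte(l, 1)
    fg <- which(y == 1)
    if (length(fg) > 0) {
      i <- sample(fg, 1)
      p2 <- p; p2[i] <- min(1, p[i] + 0.2)
      expect_lte(dice_loss(p2, y), l + 1e-12)
    }
  }
})

test_that("focal loss reproduces hand-evaluated cases and reduces to
           cross-entropy at gamma 0", {
  # single foreground pixel, p 0.5: 0.8 * 0.25 * log 2
  expect_equal(focal_loss(matrix(0.5), matrix(1), alpha = 0.8, gamma = 2),
               0.2 * log(2), tolerance = 1e-12)
  # perfect prediction: zero loss
  y <- matrix(rbinom(25, 1, .4), 5)
  expect_equal(focal_loss(y, y), 0)
  # gamma 0 / alpha -> 1 limit: plain summed cross-entropy on both classes
  set.seed(22)
  p <- matrix(runif(25, .05, .95), 5)
  a <- 1 - 1e-12
  ce_sum <- -sum(ifelse(y == 1, log(p), 0)) * a -
    sum(ifelse(y == 0, log(1 - p), 0)) * (1 - a)
  expect_equal(focal_loss(p, y, alpha = a, gamma = 0), ce_sum,
               tolerance = 1e-6)
  # hard zero at a true-foreground pixel is floored, not an error
  expect_true(is.finite(focal_loss(matrix(0), matrix(1))))
  expect_gte(focal_loss(p, y), 0)
})

test_that("combined segmentation loss applies the beta scale", {
  cfg <- mtsa_config()
  expect_equal(cfg$focal_scale_beta, 1 / 25000)
  # l_dice 0.5 and l_focal 25000 must combine to 1.5
  expect_equal(0.5 + cfg$focal_scale_beta * 25000, 1.5)
  y <- matrix(rbinom(96 * 96, 1, .05), 96)
  p <- matrix(runif(96 * 96), 96)
  sl <- seg_loss(p, y, cfg)
  expect_equal(sl$l_gtv, sl$l_dice + cfg$focal_scale_beta * sl$l_focal,
               tolerance = 1e-9)
  cfg0 <- mtsa_config(focal_scale_beta = 0)
  expect_equal(seg_loss(p, y, cfg0)$l_gtv, seg_loss(p, y, cfg0)$l_dice)
  # near-perfect prediction drives the combined loss to ~0
  pp <- pmin(pmax(y, 1e-4), 1 - 1e-4)
  expect_lt(seg_loss(pp, y, cfg)$l_gtv, 0.01)
})

test_that("cross-entropy reproduces hand-evaluated cases", {
  expect_equal(ce_loss(c(0.5, 0.5), 0L), log(2), tolerance = 1e-9)
  expect_equal(ce_loss(c(0.5, 0.5), 1L), log(2), tolerance = 1e-9)
  expect_equal(ce_loss(c(0, 1), 1L), 0, tolerance = 1e-6)
  expect_equal(ce_loss(c(0.9, 0.1), 1L), 2.302585, tolerance = 1e-6)
  q <- rbind(c(.9, .1), c(.2, .8))
  expect_equal(ce_loss(q, c(1L, 1L)), mean(c(-log(.1), -log(.8))),
               tolerance = 1e-9)
  expect_error(ce_loss(c(.6, .6), 1L), "sum to 1")
})

test_that("joint loss reproduces hand-evaluated cases in both modes", {
  expect_equal(joint_loss(1, 1, 1, 1, "uncertainty"), 1.0)
  expect_equal(joint_loss(1, 1, 1, 2, "uncertainty"), 1.318147,
               tolerance = 1e-6)
  expect_equal(joint_loss(0.8, 0.4, mode = "equal"), 0.6)
  expect_error(joint_loss(1, 1, 0, 1, "uncertainty"), "positive")
})

test_that("sigma at the analytic optimum satisfies sigma^2 = task loss", {
  l_gtv <- 0.7; l_egfr <- 1.9
  grid <- seq(0.05, 3, by = 1e-3)
  best_g <- grid[which.min(vapply(grid, function(s)
    joint_loss(l_gtv, l_egfr, s, 1), numeric(1)))]
  best_e <- grid[which.min(vapply(grid, function(s)
    joint_loss(l_gtv, l_egfr, 1, s), numeric(1)))]
  expect_equal(best_g^2, l_gtv, tolerance = 5e-3)
  expect_equal(best_e^2, l_egfr, tolerance = 5e-3)
})

test_that("joint loss gradients w.r.t. log-variance match finite differences", {
  jw <- mtsanet:::joint_weights
  for (case in list(c(0.7, 1.9), c(0.1, 3.0), c(2.5, 0.01))) {
    s <- c(0.3, -0.4)
    ana <- jw(case[1], case[2], s, "uncertainty")$ds
    for (i in 1:2) {
      h <- 1e-6
      sp <- s; sp[i] <- s[i] + h
      sm <- s; sm[i] <- s[i] - h
      fd <- (jw(case[1], case[2], sp, "uncertainty")$joint -
               jw(case[1], case[2], sm, "uncertainty")$joint) / (2 * h)
      expect_equal(ana[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("batched segmentation/classification loss gradients match finite
           differences", {
  set.seed(23)
  cfg <- mtsa_config()
  p <- array(runif(2 * 6 * 6, 0.05, 0.95), c(2, 6, 6))
  y <- array(rbinom(2 * 6 * 6, 1, 0.3), c(2, 6, 6))
  sg <- mtsanet:::seg_loss_grad_b(p, y, cfg)
  # the batched means agree with the exported per-slice losses
  expect_equal(sg$l_dice,
               mean(c(dice_loss(p[1, , ], y[1, , ], cfg$dice_epsilon),
                      dice_loss(p[2, , ], y[2, , ], cfg$dice_epsilon))),
               tolerance = 1e-12)
  expect_equal(sg$l_focal,
               mean(c(focal_loss(p[1, , ], y[1, , ], cfg$focal_alpha,
                                 cfg$focal_gamma, cfg$prob_floor),
                      focal_loss(p[2, , ], y[2, , ], cfg$focal_alpha,
                                 cfg$focal_gamma, cfg$prob_floor))),
               tolerance = 1e-6)
  h <- 1e-6
  for (k in sample(length(p), 10)) {
    pp <- p; pp[k] <- p[k] + h
    pm <- p; pm[k] <- p[k] - h
    fd <- (mtsanet:::seg_loss_grad_b(pp, y, cfg)$l_gtv -
             mtsanet:::seg_loss_grad_b(pm, y, cfg)$l_gtv) / (2 * h)
    expect_equal(sg$dp[k], fd, tolerance = 1e-4)
  }
  q <- mtsanet:::softmax_rows(matrix(rnorm(8), 4, 2))
  lb <- c(0L, 1L, 1L, 0L)
  ce <- mtsanet:::ce_loss_grad_b(q, lb)
  expect_equal(ce$l, ce_loss(q, lb), tolerance = 1e-12)
})
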