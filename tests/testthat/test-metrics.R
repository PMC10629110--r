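test_that("Dice score matches hand counts and conventions", {
  m <- matrix(0L, 8, 8)
  a <- m; a[3:4, 3:4] <- 1L                 # 2x2 square, area 4
  b <- m; b[3:4, 4:5] <- 1L                 # shifted one column, overlap 2
  expect_equal(dice_score(a, b), 2 * 2 / (4 + 4))
  expect_equal(dice_score(a, a), 1)
  d <- m; d[7:8, 7:8] <- 1L
  expect_equal(dice_score(a, d), 0)
  expect_equal(dice_score(m, m), 1)         # both empty
  expect_error(dice_score(a, matrix(0L, 4, 4)), "mismatch")
})

test_that("Dice is symmetric and harmonically tied to pixel precision/recall", {
  set.seed(31)
  for (rep in 1:20) {
    a <- random_mask(10, 10); b <- random_mask(10, 10)
    expect_equal(dice_score(a, b), dice_score(b, a))
    pr <- pixel_precision_recall(a, b)
    if (pr["precision"] + pr["recall"] > 0 && sum(a) > 0 && sum(b) > 0) {
      expect_equal(dice_score(a, b),
                   2 * pr["precision"] * pr["recall"] /
                     (pr["precision"] + pr["recall"]),
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("HD95 reproduces simple geometric cases", {
  m <- matrix(0L, 12, 12)
  a <- m; a[4:7, 4:7] <- 1L
  expect_equal(hd95(a, a), 0)
  p1 <- m; p1[3, 3] <- 1L
  p2 <- m; p2[3, 6] <- 1L                    # single pixels 3 apart
  expect_equal(hd95(p1, p2), 3)
  expect_equal(hd95(p1, p2, spacing = c(1, 0.5)), 1.5)
})

test_that("HD95 equals the all-pairs percentile oracle on random masks", {
  set.seed(32)
  n_done <- 0
  while (n_done < 50) {
    nr <- sample(8:32, 1); nc <- sample(8:32, 1)
    a <- random_mask(nr, nc, runif(1, 0.1, 0.5))
    b <- random_mask(nr, nc, runif(1, 0.1, 0.5))
    if (sum(a) == 0 || sum(b) == 0) next
    sp <- sample(list(c(1, 1), c(0.7, 1.3)), 1)[[1]]
    expect_equal(hd95(a, b, sp), oracle_hd95(a, b, sp), tolerance = 1e-9)
    n_done <- n_done + 1
  }
  # 10x10 square vs the same square shifted two columns
  m <- matrix(0L, 20, 20)
  a <- m; a[6:15, 4:13] <- 1L
  b <- m; b[6:15, 6:15] <- 1L
  expect_equal(hd95(a, b), oracle_hd95(a, b), tolerance = 1e-9)
  expect_equal(hd95(a, b), hd95(b, a))
})

test_that("HD95 empty-mask conventions", {
  m <- matrix(0L, 10, 10)
  a <- m; a[4, 4] <- 1L
  expect_equal(hd95(m, m), 0)
  h <- hd95(a, m)
  expect_equal(as.numeric(h), sqrt(200))     # image diagonal sentinel
  expect_true(isTRUE(attr(h, "degenerate")))
})

test_that("pixel precision/recall matches the loop oracle and conventions", {
  set.seed(33)
  for (rep in 1:20) {
    a <- random_mask(9, 9); b <- random_mask(9, 9)
    cc <- oracle_pixel_counts(a, b)
    pr <- pixel_precision_recall(a, b)
    want_p <- if (cc["tp"] + cc["fp"] == 0) as.numeric(cc["fn"] == 0) else
      cc["tp"] / (cc["tp"] + cc["fp"])
    want_r <- if (cc["tp"] + cc["fn"] == 0) as.numeric(cc["fp"] == 0) else
      cc["tp"] / (cc["tp"] + cc["fn"])
    expect_equal(pr, c(precision = unname(want_p), recall = unname(want_r)))
  }
  m <- matrix(0L, 6, 6)
  a <- m; a[2:3, 2:3] <- 1L
  expect_equal(pixel_precision_recall(a, a),
               c(precision = 1, recall = 1))
  big <- m; big[2:3, 2:5] <- 1L              # pred strictly contains true
  expect_equal(pixel_precision_recall(big, a),
               c(precision = 0.5, recall = 1))
  expect_equal(pixel_precision_recall(m, m), c(precision = 1, recall = 1))
})

test_that("patient-level report reproduces the published internal-test row", {
  # confusion counts uniquely consistent with 33 patients / 19 mutants and
  # the printed precision, recall and accuracy of the proposed model
  truths <- c(rep(1, 19), rep(0, 14))
  preds <- c(rep(1, 16), rep(0, 3), rep(1, 1), rep(0, 13))
  expect_equal(confusion_counts(preds, truths),
               c(tp = 16L, fp = 1L, fn = 3L, tn = 13L))
  rep_ <- classification_report(preds, truths)
  expect_equal(round(rep_["accuracy"], 4), c(accuracy = 0.8788))
  expect_equal(round(rep_["precision"], 4), c(precision = 0.9412))
  expect_equal(round(rep_["recall"], 4), c(recall = 0.8421))
  expect_equal(round(rep_["f1"], 4), c(f1 = 0.8889))
})

test_that("classification report degenerate cases and harmonic identity", {
  expect_equal(classification_report(c(1, 0, 1), c(1, 0, 1)),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_equal(classification_report(c(0, 1), c(1, 0))[["accuracy"]], 0)
  set.seed(34)
  for (rep in 1:20) {
    t_ <- rbinom(12, 1, 0.5); p_ <- rbinom(12, 1, 0.5)
    r <- classification_report(p_, t_)
    if (r["precision"] + r["recall"] > 0)
      expect_equal(r[["f1"]],
                   2 * r[["precision"]] * r[["recall"]] /
                     (r[["precision"]] + r[["recall"]]),
                   tolerance = 1e-9)
  }
  expect_error(classification_report(integer(0), integer(0)), "non-empty")
})
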