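test_that("early stopping keeps the best epoch and waits out the patience", {
  # validation loss improves strictly for 5 epochs, then goes flat:
  # training must stop at epoch 25 (5 + patience 20) with epoch 5 retained
  vals <- c(1.0, 0.9, 0.8, 0.7, 0.6, rep(0.6, 40))
  state <- list(best = Inf, best_epoch = 0L, wait = 0L)
  stopped_at <- NA_integer_
  for (ep in seq_along(vals)) {
    state <- mtsanet:::update_best(state, ep, vals[ep], patience = 20L)
    if (state$stop) { stopped_at <- ep; break }
  }
  expect_identical(stopped_at, 25L)
  expect_identical(state$best_epoch, 5L)
  expect_equal(state$best, 0.6)
  # an improvement below min_delta does not reset the patience counter
  s2 <- list(best = 0.5, best_epoch = 3L, wait = 7L)
  s2 <- mtsanet:::update_best(s2, 11L, 0.5 - 1e-9, patience = 20L,
                              min_delta = 1e-6)
  expect_false(s2$improved)
  expect_identical(s2$wait, 8L)
})

test_that("cohort splits are patient-level, seeded and disjoint", {
  pp <- tiny_phantom()
  co <- generate_cohort(20, pp, seed = 13)
  sp <- split_cohort(co, 5, seed = 1)
  expect_length(sp$train, 15L)
  expect_length(sp$val, 5L)
  ids <- function(x) vapply(x, function(p) p$patient_id, character(1))
  expect_length(intersect(ids(sp$train), ids(sp$val)), 0L)
  sp2 <- split_cohort(co, 5, seed = 1)
  expect_identical(ids(sp2$val), ids(sp$val))
  sp3 <- split_cohort(co, 5, seed = 2)
  expect_false(identical(ids(sp3$val), ids(sp$val)))
  expect_error(split_cohort(co, 20, seed = 1), "smaller than cohort size")
})

make_tiny_fit <- function(seed = 0L, epochs = 2L, ...) {
  pp <- tiny_phantom(seed = seed)
  co <- generate_cohort(8, pp, seed = seed)
  cfg <- tiny_config(seed = seed)
  sp <- split_cohort(co, 2, seed = seed)
  list(model = mtsa_fit(sp$train, sp$val, cfg, epochs = epochs, ...),
       cohort = co, cfg = cfg)
}

test_that("training is reproducible under a fixed seed", {
  a <- make_tiny_fit(seed = 3L)
  b <- make_tiny_fit(seed = 3L)
  expect_identical(a$model$history, b$model$history)
  expect_identical(a$model$params, b$model$params)
  expect_true(a$model$trained)
  h <- a$model$history
  expect_lte(nrow(h), a$model$best_epoch + a$cfg$patience + 1L)
  expect_true(all(is.finite(h$val_loss)))
  expect_true(all(h$sigma_gtv > 0 & h$sigma_egfr > 0))
})

test_that("checkpoints round-trip to identical predictions", {
  fit <- make_tiny_fit(seed = 4L)
  path <- tempfile(fileext = ".rds")
  save_weights(fit$model, path)
  back <- load_weights(path)
  pat <- fit$cohort[[1]]
  p1 <- predict(fit$model, pat)
  p2 <- predict(back, pat)
  expect_identical(p1$call$label, p2$call$label)
  expect_equal(p1$call$mean_prob, p2$call$mean_prob, tolerance = 1e-12)
  expect_equal(p1$slices[[1]]$seg_prob, p2$slices[[1]]$seg_prob,
               tolerance = 1e-12)
  expect_error(load_weights({
    f <- tempfile(); saveRDS(list(a = 1), f); f
  }), "not a recognized")
})

test_that("a patient's call depends only on its own slices and inference is
           deterministic", {
  fit <- make_tiny_fit(seed = 5L)
  co <- fit$cohort
  alone <- predict(fit$model, co[[2]])
  together <- predict(fit$model, co[1:3])[[2]]
  expect_equal(alone$call$mean_prob, together$call$mean_prob,
               tolerance = 1e-12)
  expect_identical(alone$call$label, together$call$label)
  again <- predict(fit$model, co[[2]])
  expect_identical(again$slices[[1]]$seg_mask, alone$slices[[1]]$seg_mask)
})

test_that("evaluation reports well-formed metrics", {
  fit <- make_tiny_fit(seed = 6L)
  ev <- evaluate_cohort(fit$model, fit$cohort[1:4])
  expect_s3_class(ev, "mtsa_eval")
  expect_true(all(ev$seg[c("dice", "precision", "recall")] >= 0 &
                    ev$seg[c("dice", "precision", "recall")] <= 1))
  expect_true(all(ev$cls >= 0 & ev$cls <= 1))
  expect_identical(nrow(ev$per_patient), 4L)
  expect_true(all(ev$per_patient$label %in% c(0L, 1L)))
})

test_that("joint training is no worse than the classifier-only ablation", {
  # the premise the phantom encodes: genotype signal lives inside lesions,
  # so learning to segment them should help (or at least not hurt) the
  # classifier; compared over 5 seeds at small scale
  pp <- phantom_params(image_size = 48L, lesion_radius = c(4L, 9L),
                       slices_per_patient = c(2L, 4L))
  cfg <- mtsa_config(input_size = 48L, stage_channels = c(4L, 8L, 8L, 16L, 16L),
                     num_heads = 4L, patch_grid = 3L, pool_kernel = 3L,
                     mlp_hidden = 16L, batch_size = 8L)
  acc_mt <- c(); acc_cls <- c()
  for (seed in 1:5) {
    co <- generate_cohort(26, pp, seed = seed)
    test <- co[21:26]
    sp <- split_cohort(co[1:20], 4, seed = seed)
    cfg$seed <- seed
    m_mt <- mtsa_fit(sp$train, sp$val, cfg, epochs = 8L)
    m_cl <- mtsa_fit(sp$train, sp$val, cfg, epochs = 8L,
                     branches = "classifier_only")
    acc_mt <- c(acc_mt, evaluate_cohort(m_mt, test)$cls["accuracy"])
    acc_cls <- c(acc_cls, evaluate_cohort(m_cl, test)$cls["accuracy"])
  }
  expect_gte(median(acc_mt), median(acc_cls))
})
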