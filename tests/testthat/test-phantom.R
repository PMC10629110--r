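test_that("phantom patients are reproducible and internally consistent", {
  pp <- tiny_phantom()
  a <- generate_patient(pp, "pA", seed = 5)
  b <- generate_patient(pp, "pA", seed = 5)
  expect_identical(a, b)                      # bit-identical under one seed
  c_ <- generate_patient(pp, "pA", seed = 6)
  expect_false(identical(a$slices[[1]]$image, c_$slices[[1]]$image))
  for (s in a$slices) {
    expect_gt(sum(s$mask), 0)                 # every emitted slice has lesion
    expect_identical(dim(s$image), dim(s$mask))
    # lesion pixels are brighter on average than the rest of the slice
    expect_gt(mean(s$image[s$mask == 1]), mean(s$image[s$mask == 0]))
  }
})

test_that("mask area stays within the bounds implied by the radius range", {
  pp <- tiny_phantom(lesions_per_slice = c(1L, 2L))
  # continuous-area bounds with a half-pixel margin for off-grid centres
  lo <- floor(pi * (pp$lesion_radius[1] - 0.5)^2)
  hi <- ceiling(2 * pi * (pp$lesion_radius[2] + 0.5)^2)
  for (i in 1:5) {
    p <- generate_patient(pp, "p", seed = i)
    for (s in p$slices) {
      expect_gte(sum(s$mask), lo)
      expect_lte(sum(s$mask), hi)
    }
  }
})

test_that("cohorts are seeded, disjoint, and mutate at the configured rate", {
  pp <- tiny_phantom()
  co1 <- generate_cohort(12, pp, seed = 1)
  co2 <- generate_cohort(12, pp, seed = 1)
  expect_identical(co1, co2)
  co3 <- generate_cohort(12, pp, seed = 2)
  imgs1 <- lapply(co1, function(p) p$slices[[1]]$image)
  imgs3 <- lapply(co3, function(p) p$slices[[1]]$image)
  for (i in seq_along(imgs1)) expect_false(identical(imgs1[[i]], imgs3[[i]]))
  expect_length(generate_cohort(1, pp), 1L)
  expect_error(generate_cohort(0, pp), ">= 1")
  # mutant count within the central 99% binomial range at n = 100
  co <- generate_cohort(100, phantom_params(), seed = 0)
  n_mut <- sum(vapply(co, function(p) p$genotype, integer(1)))
  expect_gte(n_mut, qbinom(0.005, 100, 0.5))
  expect_lte(n_mut, qbinom(0.995, 100, 0.5))
})

test_that("a null effect size removes the genotype signal", {
  pp <- phantom_params(effect_size = 0, image_size = 64L,
                       lesion_radius = c(4L, 10L))
  co <- generate_cohort(60, pp, seed = 3)
  d <- separability_check(co)
  expect_lt(abs(d), 0.3)
  st <- phantom_statistics(co)
  # two-sample location test cannot tell the classes apart
  pv <- t.test(stat ~ genotype, data = st)$p.value
  expect_gt(pv, 0.01)
})

test_that("the default effect size yields a learnable, threshold-separable
           signal", {
  co <- generate_cohort(100, phantom_params(), seed = 0)
  expect_gt(separability_check(co), 1)
  st <- phantom_statistics(co)
  thr <- mean(tapply(st$stat, st$genotype, mean))
  acc <- mean((st$stat > thr) == (st$genotype == 1))
  expect_gte(acc, 0.85)
})

test_that("separation is invariant to affine intensity transforms", {
  pp <- tiny_phantom(slices_per_patient = c(2L, 3L))
  co <- generate_cohort(30, pp, seed = 4)
  d0 <- separability_check(co)
  shifted <- lapply(co, function(p) {
    p$slices <- lapply(p$slices, function(s) {
      s$image <- 3.7 * s$image + 42
      s
    })
    p
  })
  expect_equal(separability_check(shifted), d0, tolerance = 1e-6)
  single <- co[vapply(co, function(p) p$genotype, integer(1)) == 1]
  expect_error(separability_check(single), "single class")
})

test_that("texture effect is detected by its matching statistic", {
  pp <- phantom_params(effect = "texture_frequency", image_size = 64L,
                       lesion_radius = c(5L, 10L), effect_size = 0.8)
  co <- generate_cohort(40, pp, seed = 5)
  expect_gt(abs(separability_check(co, effect = "texture_frequency")), 1)
})
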