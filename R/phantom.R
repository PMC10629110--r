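# Seeded synthetic phantom cohorts.
#
# Each patient is a short stack of 2-D slices mimicking contrast-enhanced MR
# of brain metastases at desk scale: a smooth elliptical "brain" background
# with a low-frequency intensity field and additive Gaussian noise, plus
# 1-3 bright disk lesions per slice with exact ground-truth masks. The
# genotype signal lives ONLY inside lesions: with the default
# ring-enhancement effect, mutant lesions have a bright rim and darker core
# (rim/core contrast grows with effect_size), wild-type lesions enhance
# uniformly; the alternative texture effect gives mutant lesions a
# high-frequency intensity texture. effect_size = 0 makes the classes
# indistinguishable by construction. Every slice carries at least one
# lesion, mirroring a dataset from which lesion-free slices were removed.

#' Phantom cohort parameters
#'
#' @param image_size square slice side in pixels.
#' @param slices_per_patient inclusive integer range.
#' @param lesions_per_slice inclusive integer range.
#' @param lesion_radius inclusive radius range in pixels.
#' @param background_noise_sd additive Gaussian noise sd (intensity units;
#'   background tissue is ~0.35, lesions enhance by ~0.45).
#' @param mutant_fraction probability that a patient is mutant.
#' @param effect \code{"ring_enhancement"} or \code{"texture_frequency"}.
#' @param effect_size non-negative contrast of the mutant effect; 0 removes
#'   the class signal entirely.
#' @param seed integer base seed.
#' @return an object of class \code{phantom_params}.
#' @export
phantom_params <- function(image_size = 96L,
                           slices_per_patient = c(3L, 8L),
                           lesions_per_slice = c(1L, 3L),
                           lesion_radius = c(4L, 14L),
                           background_noise_sd = 0.03,
                           mutant_fraction = 0.5,
                           effect = c("ring_enhancement", "texture_frequency"),
                           effect_size = 0.8,
                           seed = 0L) {
  effect <- match.arg(effect)
  p <- list(image_size = as.integer(image_size),
            slices_per_patient = as.integer(slices_per_patient),
            lesions_per_slice = as.integer(lesions_per_slice),
            lesion_radius = as.integer(lesion_radius),
            background_noise_sd = as.numeric(background_noise_sd),
            mutant_fraction = as.numeric(mutant_fraction),
            effect = effect,
            effect_size = as.numeric(effect_size),
            seed = as.integer(seed))
  if (p$slices_per_patient[1] > p$slices_per_patient[2] ||
      p$lesions_per_slice[1] > p$lesions_per_slice[2] ||
      p$lesion_radius[1] > p$lesion_radius[2])
    stop("ranges must be non-empty (lo <= hi)")
  if (p$effect_size < 0) stop("effect_size must be >= 0")
  if (p$mutant_fraction <= 0 || p$mutant_fraction >= 1)
    stop("mutant_fraction must lie in (0,1)")
  if (p$lesion_radius[2] * 2L + 8L > p$image_size)
    stop("lesion radius incompatible with image size")
  class(p) <- "phantom_params"
  p
}

rand_int <- function(lo, hi) lo + floor(stats::runif(1) * (hi - lo + 1))

# smooth elliptical background with a low-frequency field
render_background <- function(sz) {
  rr <- matrix(seq_len(sz), sz, sz)
  cc <- t(rr)
  cy <- sz / 2 + stats::runif(1, -2, 2)
  cx <- sz / 2 + stats::runif(1, -2, 2)
  ay <- sz * stats::runif(1, 0.38, 0.44)
  ax <- sz * stats::runif(1, 0.34, 0.40)
  inside <- ((rr - cy) / ay)^2 + ((cc - cx) / ax)^2 <= 1
  field <- matrix(0, sz, sz)
  for (k in 1:3) {
    fy <- stats::runif(1, 0.5, 2) * 2 * pi / sz
    fx <- stats::runif(1, 0.5, 2) * 2 * pi / sz
    ph <- stats::runif(2, 0, 2 * pi)
    field <- field + stats::runif(1, 0.01, 0.04) *
      sin(fy * rr + ph[1]) * sin(fx * cc + ph[2])
  }
  img <- 0.02 + inside * (0.33 + field)
  list(img = img, inside = inside, cy = cy, cx = cx, ay = ay, ax = ax)
}

# draw one slice: background + lesions; returns image and exact mask
render_slice <- function(p, genotype) {
  sz <- p$image_size
  bg <- render_background(sz)
  img <- bg$img
  mask <- matrix(0L, sz, sz)
  rr <- matrix(seq_len(sz), sz, sz)
  cc <- t(rr)
  n_les <- rand_int(p$lesions_per_slice[1], p$lesions_per_slice[2])
  for (l in seq_len(n_les)) {
    R <- rand_int(p$lesion_radius[1], p$lesion_radius[2])
    # rejection-sample a centre comfortably inside the brain ellipse
    repeat {
      y0 <- stats::runif(1, R + 2, sz - R - 2)
      x0 <- stats::runif(1, R + 2, sz - R - 2)
      if (((y0 - bg$cy) / (bg$ay - R))^2 + ((x0 - bg$cx) / (bg$ax - R))^2 <= 0.85)
        break
    }
    rho2 <- (rr - y0)^2 + (cc - x0)^2
    disk <- rho2 <= R^2
    amp <- 0.45 * stats::runif(1, 0.9, 1.1)
    if (genotype == 1L && p$effect_size > 0) {
      if (p$effect == "ring_enhancement") {
        rim <- disk & rho2 > (0.65 * R)^2
        core <- disk & !rim
        img[core] <- img[core] + amp * (1 - 0.5 * p$effect_size)
        img[rim] <- img[rim] + amp * (1 + 0.5 * p$effect_size)
      } else {
        tex <- 1 + 0.5 * p$effect_size * sin(2 * pi * rr / 3) * sin(2 * pi * cc / 3)
        img[disk] <- img[disk] + amp * tex[disk]
      }
    } else {
      img[disk] <- img[disk] + amp
    }
    mask[disk] <- 1L
  }
  img <- img + stats::rnorm(sz * sz, sd = p$background_noise_sd)
  img <- pmax(img, 0)
  list(image = img, mask = mask)
}

#' Generate one phantom patient
#'
#' Deterministic given \code{(params, seed)}: the genotype is drawn first
#' (mutant with probability \code{mutant_fraction}), then each slice is
#' rendered. Every slice has a non-empty mask by construction.
#'
#' @param params a [phantom_params()] object.
#' @param patient_id identifier.
#' @param seed integer seed for this patient's stream.
#' @return a [patient_case()].
#' @export
generate_patient <- function(params, patient_id = "p1", seed = params$seed) {
  with_seed(seed, {
    genotype <- as.integer(stats::runif(1) < params$mutant_fraction)
    n_slices <- rand_int(params$slices_per_patient[1],
                         params$slices_per_patient[2])
    slices <- vector("list", n_slices)
    for (s in seq_len(n_slices)) {
      rs <- render_slice(params, genotype)
      slices[[s]] <- slice_sample(rs$image, rs$mask, patient_id, genotype,
                                  slice_index = s - 1L)
    }
    patient_case(patient_id, slices, genotype)
  })
}

#' Generate a phantom cohort
#'
#' Patients come from disjoint sequential sub-streams of the base seed, so
#' a cohort is fully reproducible from \code{(params, seed)} and cohorts
#' with different base seeds are disjoint.
#'
#' @param n_patients number of patients (>= 1).
#' @param params a [phantom_params()] object.
#' @param seed base seed; defaults to \code{params$seed}.
#' @return list of [patient_case()] objects.
#' @export
generate_cohort <- function(n_patients, params = phantom_params(),
                            seed = params$seed) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  lapply(seq_len(n_patients), function(i) {
    generate_patient(params, patient_id = sprintf("pt%03d", i),
                     seed = seed * 1000003L + i)
  })
}

# 4-neighbour binary erosion, k iterations
erode_mask <- function(m, k = 1L) {
  for (i in seq_len(k)) {
    nr <- nrow(m); nc <- ncol(m)
    up <- rbind(m[-1, , drop = FALSE], 0)
    dn <- rbind(0, m[-nr, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], 0)
    rt <- cbind(0, m[, -nc, drop = FALSE])
    m <- (m == 1 & up == 1 & dn == 1 & lf == 1 & rt == 1) * 1L
  }
  m
}

# 3x3 box blur (edge-replicated)
box_blur3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (a in 0:2) for (b in 0:2)
    acc <- acc + pad[a + seq_len(nr), b + seq_len(nc)]
  acc / 9
}

# per-slice lesion appearance statistic; background-corrected so it is
# invariant to affine intensity transforms of the whole image
slice_lesion_stat <- function(image, mask, effect) {
  core <- erode_mask(mask, 2L)
  rim <- (mask == 1 & core == 0) * 1L
  if (sum(core) < 4 || sum(rim) < 4) return(NA_real_)
  bg <- stats::median(image[mask == 0])
  if (effect == "ring_enhancement") {
    (mean(image[rim == 1]) - bg) / max(mean(image[core == 1]) - bg, 1e-6)
  } else {
    hf <- image - box_blur3(image)
    sqrt(mean(hf[core == 1]^2)) / max(mean(image[core == 1]) - bg, 1e-6)
  }
}

#' Per-patient lesion appearance statistics
#'
#' The mean over slices of a background-corrected lesion statistic: the
#' rim-to-core enhancement ratio (ring effect) or the normalized
#' high-frequency energy inside the lesion core (texture effect).
#'
#' @param cohort list of [patient_case()] objects.
#' @param effect which statistic to compute.
#' @return data frame with \code{patient_id}, \code{genotype}, \code{stat}.
#' @export
phantom_statistics <- function(cohort,
                               effect = c("ring_enhancement",
                                          "texture_frequency")) {
  effect <- match.arg(effect)
  rows <- lapply(cohort, function(p) {
    st <- vapply(p$slices,
                 function(s) slice_lesion_stat(s$image, s$mask, effect),
                 numeric(1))
    data.frame(patient_id = p$patient_id, genotype = p$genotype,
               stat = mean(st, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Class separation of the phantom genotype signal
#'
#' Standardized mean difference (pooled-sd Cohen's d) of the per-patient
#' lesion statistic between mutant and wild patients. Used to calibrate
#' \code{effect_size} so the classification task is learnable but not
#' trivial.
#'
#' @param cohort list of [patient_case()] objects.
#' @param effect statistic matching the generator's effect.
#' @return scalar standardized mean difference.
#' @export
separability_check <- function(cohort,
                               effect = c("ring_enhancement",
                                          "texture_frequency")) {
  effect <- match.arg(effect)
  st <- phantom_statistics(cohort, effect)
  g1 <- st$stat[st$genotype == 1]
  g0 <- st$stat[st$genotype == 0]
  if (length(g1) == 0 || length(g0) == 0)
    stop("cohort contains a single class; separation undefined")
  sp <- sqrt(((length(g1) - 1) * stats::var(g1) +
                (length(g0) - 1) * stats::var(g0)) /
               (length(g1) + length(g0) - 2))
  (mean(g1) - mean(g0)) / max(sp, 1e-12)
}
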