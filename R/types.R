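# Shared data model: slices, patients, predictions.
#
# Images are numeric matrices (rows x cols); masks are {0,1} integer matrices
# of the same shape; coordinates are 0-based (row, col) with origin top-left
# when exported. Genotype coding: 1 = mutant (positive class), 0 = wild-type.

#' A single training slice
#'
#' The training atom: one 2-D image with its binary lesion mask, the owning
#' patient id, the patient's genotype label and the slice position.
#'
#' @param image numeric matrix (rows x cols), normalized intensities.
#' @param mask binary matrix of the same shape, 1 = lesion foreground.
#' @param patient_id identifier string.
#' @param genotype 0 (wild-type) or 1 (mutant).
#' @param slice_index non-negative integer position in the stack.
#' @return an object of class \code{slice_sample}.
#' @export
slice_sample <- function(image, mask, patient_id, genotype, slice_index) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ: ", paste(dim(image), collapse = "x"),
         " vs ", paste(dim(mask), collapse = "x"))
  if (!all(mask %in% c(0, 1))) stop("non-binary mask: values outside {0,1}")
  if (!genotype %in% c(0, 1)) stop("genotype must be 0 (wild) or 1 (mutant)")
  if (slice_index < 0) stop("slice_index must be >= 0")
  structure(list(image = image, mask = mask,
                 patient_id = as.character(patient_id),
                 genotype = as.integer(genotype),
                 slice_index = as.integer(slice_index)),
            class = "slice_sample")
}

#' A patient: an ordered slice stack with one genotype label
#'
#' @param patient_id identifier string.
#' @param slices list of [slice_sample()] objects, strictly increasing
#'   \code{slice_index}, all sharing \code{patient_id} and genotype.
#' @param genotype 0 or 1.
#' @return an object of class \code{patient_case}.
#' @export
patient_case <- function(patient_id, slices, genotype) {
  if (length(slices) < 1L) stop("patient needs at least one slice")
  patient_id <- as.character(patient_id)
  genotype <- as.integer(genotype)
  idx <- vapply(slices, function(s) s$slice_index, integer(1))
  if (any(diff(idx) <= 0L)) stop("slice_index must be strictly increasing")
  for (s in slices) {
    if (!inherits(s, "slice_sample")) stop("slices must be slice_sample objects")
    if (s$patient_id != patient_id) stop("slice patient_id mismatch")
    if (s$genotype != genotype) stop("slice genotype mismatch")
  }
  structure(list(patient_id = patient_id, slices = slices,
                 genotype = genotype),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  d <- dim(x$slices[[1]]$image)
  cat(sprintf("patient %s: %d slice(s) of %dx%d, genotype %s\n",
              x$patient_id, length(x$slices), d[1], d[2],
              if (x$genotype == 1L) "mutant" else "wild"))
  invisible(x)
}

#' Per-slice model output
#'
#' @param seg_prob numeric matrix of foreground probabilities in [0,1].
#' @param mutation_prob scalar mutant-class probability.
#' @param slice_index integer slice position.
#' @param seg_threshold threshold binarizing \code{seg_prob} (strict >).
#' @return an object of class \code{slice_prediction} with fields
#'   \code{seg_prob}, \code{seg_mask}, \code{mutation_prob},
#'   \code{slice_index}.
#' @export
slice_prediction <- function(seg_prob, mutation_prob, slice_index,
                             seg_threshold = 0.5) {
  if (any(seg_prob < 0 | seg_prob > 1)) stop("seg_prob outside [0,1]")
  if (mutation_prob < 0 || mutation_prob > 1)
    stop("mutation_prob outside [0,1]")
  structure(list(seg_prob = seg_prob,
                 seg_mask = (seg_prob > seg_threshold) * 1L,
                 mutation_prob = as.numeric(mutation_prob),
                 slice_index = as.integer(slice_index)),
            class = "slice_prediction")
}

# z-score normalize one slice; constant slices map to all zeros
zscore_slice <- function(img) {
  s <- stats::sd(img)
  if (s < 1e-12) return(img * 0)
  (img - mean(img)) / s
}

# stack a list of patient_case objects into batched tensors
cohort_tensors <- function(cohort, normalize = TRUE) {
  slices <- unlist(lapply(cohort, function(p) p$slices), recursive = FALSE)
  n <- length(slices)
  d <- dim(slices[[1]]$image)
  x <- array(0, c(n, d[1], d[2], 1L))
  y <- array(0, c(n, d[1], d[2]))
  lab <- integer(n)
  pid <- character(n)
  sidx <- integer(n)
  for (i in seq_len(n)) {
    s <- slices[[i]]
    x[i, , , 1L] <- if (normalize) zscore_slice(s$image) else s$image
    y[i, , ] <- s$mask
    lab[i] <- s$genotype
    pid[i] <- s$patient_id
    sidx[i] <- s$slice_index
  }
  list(x = x, y = y, label = lab, patient_id = pid, slice_index = sidx)
}
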