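# Slice-to-patient post-processing: slices are ranked by the area of the
# predicted lesion mask, the upper half (ceiling for odd counts) is kept,
# and the mean mutation probability of the kept slices makes the call —
# mutant only if it strictly exceeds the threshold.

#' Foreground area of a predicted mask
#'
#' @param mask binary matrix.
#' @return integer pixel count.
#' @export
slice_area <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("non-binary mask")
  as.integer(sum(mask))
}

#' Aggregate per-slice evidence into one patient-level genotype call
#'
#' Slices are sorted by predicted lesion area, descending (ties broken by
#' ascending slice index, so the result is permutation-invariant); the top
#' \code{ceiling(n/2)} slices are selected and their mutation probabilities
#' averaged. The call is mutant (1) only when the mean strictly exceeds
#' \code{threshold}; a mean of exactly \code{threshold} is wild.
#'
#' @param evidence data frame with columns \code{slice_index}, \code{area}
#'   (non-negative integers) and \code{mutation_prob} (in [0,1]); one row
#'   per slice.
#' @param threshold decision threshold, default 0.5.
#' @param patient_id optional identifier carried into the result.
#' @return an object of class \code{patient_call}: list with
#'   \code{selected_slices}, \code{mean_prob}, \code{label}.
#' @export
aggregate_patient <- function(evidence, threshold = 0.5, patient_id = NA) {
  if (NROW(evidence) == 0) stop("empty evidence list")
  stopifnot(all(c("slice_index", "area", "mutation_prob") %in% names(evidence)))
  if (any(evidence$area < 0)) stop("area must be >= 0")
  if (any(evidence$mutation_prob < 0 | evidence$mutation_prob > 1))
    stop("mutation_prob outside [0,1]")
  ord <- order(-evidence$area, evidence$slice_index)
  n_sel <- ceiling(nrow(evidence) / 2)
  sel <- ord[seq_len(n_sel)]
  mean_prob <- mean(evidence$mutation_prob[sel])
  structure(list(patient_id = patient_id,
                 selected_slices = evidence$slice_index[sel],
                 n_slices = nrow(evidence),
                 mean_prob = mean_prob,
                 label = as.integer(mean_prob > threshold)),
            class = "patient_call")
}

#' @export
print.patient_call <- function(x, ...) {
  cat(sprintf("patient %s: %d/%d slices used, mean mutation prob %.3f -> %s\n",
              x$patient_id, length(x$selected_slices), x$n_slices,
              x$mean_prob, if (x$label == 1L) "mutant" else "wild"))
  invisible(x)
}
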