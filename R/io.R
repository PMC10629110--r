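# Dataset IO.
#
# Cohorts are written as one volume pair per patient (image + mask, slices
# along the third axis) in NIfTI, or as multi-page 16-bit TIFF; genotype
# labels go to a CSV table and a YAML manifest ties records together with a
# format version tag. Loading applies the dataset rule that only
# lesion-bearing slices are kept, plus per-slice z-score normalization.

MANIFEST_VERSION <- 1L
TIFF_SCALE <- 2  # intensities are stored as value/TIFF_SCALE in [0,1]

#' Write a cohort to disk
#'
#' @param cohort list of [patient_case()] objects.
#' @param dir output directory (created if needed).
#' @param format \code{"nifti"} (lossless doubles) or \code{"tiff"}
#'   (multi-page 16-bit, intensities quantized to 1/65535 of
#'   \code{TIFF_SCALE = 2} intensity units).
#' @return path to the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "tiff")) {
  format <- match.arg(format)
  if (format == "tiff" && !requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for format = 'tiff'")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    d <- dim(p$slices[[1]]$image)
    S <- length(p$slices)
    img <- array(0, c(d, S))
    msk <- array(0L, c(d, S))
    for (s in seq_len(S)) {
      img[, , s] <- p$slices[[s]]$image
      msk[, , s] <- p$slices[[s]]$mask
    }
    ext <- if (format == "nifti") ".nii.gz" else ".tif"
    fi <- paste0(p$patient_id, "_image", ext)
    fm <- paste0(p$patient_id, "_mask", ext)
    if (format == "nifti") {
      RNifti::writeNifti(img, file.path(dir, fi))
      RNifti::writeNifti(msk, file.path(dir, fm))
    } else {
      tiff::writeTIFF(lapply(seq_len(S), function(s)
        pmin(pmax(img[, , s] / TIFF_SCALE, 0), 1)),
        file.path(dir, fi), bits.per.sample = 16L)
      tiff::writeTIFF(lapply(seq_len(S), function(s) msk[, , s] * 1.0),
                      file.path(dir, fm), bits.per.sample = 8L)
    }
    recs[[i]] <- list(patient_id = p$patient_id, image = fi, mask = fm,
                      genotype = p$genotype)
  }
  labels <- data.frame(
    patient_id = vapply(cohort, function(p) p$patient_id, character(1)),
    genotype = vapply(cohort, function(p) p$genotype, integer(1)))
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(format_version = MANIFEST_VERSION, image_format = format,
                   patients = recs)
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

read_volume <- function(path, format) {
  if (format == "nifti") {
    v <- unclass(RNifti::readNifti(path))
    d <- dim(v)
    if (length(d) == 2L) d <- c(d, 1L)   # single-slice volume
    array(as.numeric(v), d)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    v <- array(0, c(d[1], d[2], length(pages)))
    for (s in seq_along(pages)) v[, , s] <- pages[[s]]
    v
  }
}

#' Load a dataset from a manifest
#'
#' Reads each patient's image and mask volume, validates geometry and mask
#' values (\code{{0,1}} accepted directly; \code{{0,255}} rasters are
#' binarized; anything else is an error), splits the volumes into slices,
#' drops slices whose mask is empty (training and evaluation use
#' lesion-bearing slices only), optionally z-score normalizes each slice,
#' and preserves patient order.
#'
#' @param manifest_path path to a \code{manifest.yaml} from [write_cohort()].
#' @param normalize apply per-slice z-score normalization.
#' @return list of [patient_case()] objects.
#' @export
load_dataset <- function(manifest_path, normalize = TRUE) {
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$format_version) || man$format_version > MANIFEST_VERSION)
    stop("unsupported manifest version")
  format <- man$image_format
  base <- dirname(manifest_path)
  if (format == "tiff" && !requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read tiff cohorts")
  out <- vector("list", length(man$patients))
  for (i in seq_along(man$patients)) {
    rec <- man$patients[[i]]
    fi <- file.path(base, rec$image)
    fm <- file.path(base, rec$mask)
    if (!file.exists(fi)) stop("missing image file: ", fi)
    if (!file.exists(fm)) stop("missing mask file: ", fm)
    if (!rec$genotype %in% c(0, 1))
      stop("genotype must be 0 or 1 for patient ", rec$patient_id)
    img <- read_volume(fi, format)
    msk <- read_volume(fm, format)
    if (format == "tiff") img <- img * TIFF_SCALE
    if (!identical(dim(img), dim(msk)))
      stop("geometry mismatch for patient ", rec$patient_id, ": image ",
           paste(dim(img), collapse = "x"), " vs mask ",
           paste(dim(msk), collapse = "x"))
    vals <- sort(unique(as.vector(msk)))
    if (all(vals %in% c(0, 255)) && any(vals == 255)) {
      msk <- (msk > 0) * 1L
    } else if (!all(vals %in% c(0, 1))) {
      stop("non-binary mask for patient ", rec$patient_id,
           " (values: ", paste(utils::head(vals, 5), collapse = ","), ")")
    }
    slices <- list()
    for (s in seq_len(dim(img)[3])) {
      m <- matrix(as.integer(msk[, , s] > 0), dim(msk)[1], dim(msk)[2])
      if (sum(m) == 0) next  # lesion-free slice: eliminated from the dataset
      im <- img[, , s]
      if (normalize) im <- zscore_slice(im)
      slices[[length(slices) + 1L]] <-
        slice_sample(im, m, rec$patient_id, rec$genotype, slice_index = s - 1L)
    }
    if (length(slices) == 0)
      stop("patient ", rec$patient_id, " has no lesion-bearing slices")
    out[[i]] <- patient_case(rec$patient_id, slices, as.integer(rec$genotype))
  }
  out
}
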