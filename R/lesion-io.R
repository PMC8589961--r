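# Reading, validating and pre-processing binary lesion masks (NIfTI).

#' Read a set of aligned binary lesion masks
#'
#' Loads each NIfTI volume, binarizes values above 0.5 to 1, and verifies
#' that all volumes share one grid: identical dimensions and affines equal
#' to within 1e-4 mm per entry. Masks are assumed already standardized to a
#' common space; no resampling is performed.
#'
#' @param paths character vector of NIfTI file paths.
#' @param patientIds identifiers; defaults to file basenames.
#' @param expectedGrid optional integer(3); when given, volumes must match.
#' @return A [LesionVolumeSet-class].
#' @export
readMaskSet <- function(paths, patientIds = NULL, expectedGrid = NULL) {
  if (is.null(patientIds))
    patientIds <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  masks <- vector("list", length(paths))
  affine <- NULL
  refDim <- expectedGrid
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    d <- dim(img)
    if (length(d) != 3L)
      stop(sprintf("%s: expected a 3-D volume, got %d dimensions",
                   paths[i], length(d)), call. = FALSE)
    if (is.null(refDim)) refDim <- d
    if (!identical(as.integer(d), as.integer(refDim)))
      stop(sprintf("%s: grid shape (%s) does not match expected (%s)",
                   paths[i], paste(d, collapse = "x"),
                   paste(refDim, collapse = "x")), call. = FALSE)
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = c(4L, 4L))
    if (is.null(affine)) affine <- aff
    else if (max(abs(aff - affine)) > 1e-4)
      stop(sprintf("%s: affine differs from the first volume by more than 1e-4 mm",
                   paths[i]), call. = FALSE)
    masks[[i]] <- array(as.numeric(img > 0.5), dim = d)
  }
  vs <- abs(diag(affine)[1:3])
  new("LesionVolumeSet",
    patientIds = as.character(patientIds), masks = masks, affine = affine,
    voxelSizeMm = vs,
    volumesCm3 = vapply(masks, lesionVolumeCm3, 0, voxelSizeMm = vs)
  )
}

#' Write a lesion set as NIfTI volumes plus a manifest
#'
#' One NIfTI file per patient (named `<patient_id>.nii.gz`) and a
#' tab-separated manifest with columns patient_id, file, volume_cm3 plus
#' any extra per-patient columns supplied.
#'
#' @param lesions a [LesionVolumeSet-class].
#' @param dir output directory (created if needed).
#' @param extra optional data.frame of extra manifest columns (same order
#'   as patients).
#' @return The manifest path, invisibly.
#' @export
writeMaskSet <- function(lesions, dir, extra = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- if (length(lesions@patientIds))
    file.path(dir, paste0(lesions@patientIds, ".nii.gz")) else character()
  for (i in seq_along(lesions@masks)) {
    img <- RNifti::asNifti(lesions@masks[[i]])
    RNifti::pixdim(img) <- lesions@voxelSizeMm
    img <- RNifti::`qform<-`(img, structure(lesions@affine, code = 2L))
    RNifti::writeNifti(img, files[i])
  }
  manifest <- data.frame(patient_id = lesions@patientIds,
                         file = basename(files),
                         volume_cm3 = lesions@volumesCm3,
                         stringsAsFactors = FALSE)
  if (!is.null(extra)) manifest <- cbind(manifest, extra)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Smooth a binary mask along z and re-binarize
#'
#' Convolves the mask along the z axis only with a 1-D Gaussian kernel of
#' `sd = fwhmMm / (2 * sqrt(2 * log(2)))` expressed in voxels, then
#' re-binarizes at `threshold`. The kernel is truncated at +/- 4 sd and
#' renormalized to unit sum; edges are handled by nearest-edge replication
#' so lesions touching the field-of-view boundary do not shrink spuriously.
#' This mirrors the standard pre-processing step that regularises manual
#' lesion delineations.
#'
#' @param mask 3-D binary array.
#' @param fwhmMm full width at half maximum in mm (default 5).
#' @param threshold re-binarization threshold in (0, 1) (default 0.5).
#' @param voxelSizeMm numeric(3); only the z spacing is used.
#' @return A binary array of the same shape.
#' @export
smoothBinarizeZ <- function(mask, fwhmMm = 5, threshold = 0.5,
                            voxelSizeMm = c(1, 1, 1)) {
  if (fwhmMm <= 0) stop("fwhmMm must be positive", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  dz <- voxelSizeMm[3L]
  if (!is.finite(dz) || dz <= 0)
    stop("z voxel spacing must be positive", call. = FALSE)
  kern <- gaussianKernel1d(fwhmMm, dz)
  sm <- convolveZReplicate(mask, kern)
  array(as.numeric(sm >= threshold), dim = dim(mask))
}

# Truncated (+/- 4 sd), unit-sum 1-D Gaussian kernel in voxel units.
gaussianKernel1d <- function(fwhmMm, dzMm) {
  sd <- fwhmMm / (2 * sqrt(2 * log(2))) / dzMm
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k / sum(k)
}

# 1-D convolution along the third array axis with nearest-edge replication.
convolveZReplicate <- function(arr, kern) {
  d <- dim(arr)
  half <- (length(kern) - 1L) %/% 2L
  out <- array(0, dim = d)
  for (o in seq_along(kern)) {
    off <- o - half - 1L
    src <- pmin(pmax(seq_len(d[3L]) + off, 1L), d[3L])
    out <- out + kern[o] * arr[, , src, drop = FALSE]
  }
  out
}

#' Lesion volume in cubic centimetres
#'
#' @param mask 3-D binary array.
#' @param voxelSizeMm numeric(3) voxel size in mm.
#' @return Nonzero voxel count times voxel volume, in cm^3.
#' @examples
#' lesionVolumeCm3(array(1, c(10, 10, 10)), c(1, 1, 1))  # 1 cm^3
#' @export
lesionVolumeCm3 <- function(mask, voxelSizeMm) {
  sum(mask != 0) * prod(voxelSizeMm) / 1000
}
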