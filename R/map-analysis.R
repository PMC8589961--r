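# Post-statistics map operations: thresholded-map overlap, midsagittal
# mirror-homologue mapping, atlas-based cluster description, peak lookup,
# and lesion overlay counts.

#' Overlap between two thresholded maps
#'
#' Counts the voxels significant in both maps and expresses the common
#' count as a percentage of each map. An empty map gives 0 with the
#' corresponding `undefined` flag set.
#'
#' @param mapA,mapB [ThresholdedMap-class] objects on the same grid.
#' @return An [OverlapReport-class].
#' @export
mapOverlap <- function(mapA, mapB) {
  if (!identical(dim(mapA@significant), dim(mapB@significant)))
    stop("maps are not on the same grid", call. = FALSE)
  a <- mapA@significant != 0
  b <- mapB@significant != 0
  nA <- sum(a); nB <- sum(b); nC <- sum(a & b)
  new("OverlapReport",
    nCommon = as.integer(nC),
    pctOfA = if (nA > 0) 100 * nC / nA else 0,
    pctOfB = if (nB > 0) 100 * nC / nB else 0,
    undefinedA = nA == 0L, undefinedB = nB == 0L
  )
}

#' Mirror a thresholded map across the midsagittal plane
#'
#' Maps each significant voxel through world space: the voxel centre at
#' world (x, y, z) is reflected to (-x, y, z) and assigned to the voxel
#' containing that point. On grids whose voxel centres are symmetric about
#' x = 0 this is exact and an involution; otherwise nearest-voxel
#' assignment is used with a warning. Reflections landing outside the
#' field of view are dropped and counted in the provenance
#' (`mirror_dropped`). Voxel centres within half a voxel of x = 0 map to
#' themselves; [pipelineCompare()] excludes them from homologue
#' comparisons.
#'
#' @param map a [ThresholdedMap-class].
#' @return The mirrored [ThresholdedMap-class].
#' @export
mirrorHomologue <- function(map) {
  g <- dim(map@significant)
  lin <- which(map@significant != 0)
  out <- array(0, dim = g)
  nDropped <- 0L
  if (length(lin)) {
    vox <- linearVox(lin, g)
    w <- voxelToWorldMat(vox, map@affine)
    w[, 1L] <- -w[, 1L]
    v2 <- worldToVoxelMat(w, map@affine)
    offGrid <- max(abs(v2 - round(v2)))
    if (offGrid > 1e-6)
      warning(sprintf(
        "grid is not symmetric about x = 0 (max offset %.3g voxels); %s",
        offGrid, "using nearest-voxel assignment"))
    v2 <- round(v2)
    keep <- v2[, 1L] >= 1 & v2[, 1L] <= g[1L] &
      v2[, 2L] >= 1 & v2[, 2L] <= g[2L] &
      v2[, 3L] >= 1 & v2[, 3L] <= g[3L]
    nDropped <- sum(!keep)
    out[voxLinear(v2[keep, , drop = FALSE], g)] <- 1
  }
  prov <- map@provenance
  prov$mirrored <- !isTRUE(prov$mirrored)
  prov$mirror_dropped <- nDropped
  new("ThresholdedMap",
    significant = out, zCut = map@zCut,
    alphaCorrected = map@alphaCorrected,
    nSignificant = as.integer(sum(out)),
    affine = map@affine, provenance = prov
  )
}

#' World x coordinate of every voxel centre
#'
#' Utility for hemisphere membership: negative x is the left hemisphere,
#' positive x the right; |x| below half a voxel width is midline.
#'
#' @param gridShape integer(3).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return 3-D array of world x coordinates.
#' @export
worldXMap <- function(gridShape, affine) {
  lin <- seq_len(prod(gridShape))
  vox <- linearVox(lin, gridShape)
  array(voxelToWorldMat(vox, affine)[, 1L], dim = gridShape)
}

#' Atlas coverage of a thresholded map
#'
#' For every atlas ROI intersected by the map, reports the number of
#' significant voxels inside the ROI (`n_sig`) and the percentage of the
#' ROI covered (`fraction`). ROIs without significant voxels are omitted;
#' rows are sorted by `n_sig` descending. Significant voxels outside every
#' ROI are counted in the `n_outside` attribute; empty ROIs in the names
#' table are skipped with a warning.
#'
#' @param map a [ThresholdedMap-class].
#' @param atlas an [AtlasLabels-class] on the same grid.
#' @return data.frame (label, name, atlas, n_sig, fraction) with attribute
#'   `n_outside`.
#' @export
atlasFractions <- function(map, atlas) {
  validObject(atlas)
  if (!identical(dim(map@significant), dim(atlas@labelVolume)))
    stop("atlas is not on the analysis grid", call. = FALSE)
  sig <- map@significant != 0
  labs <- atlas@names
  rows <- lapply(seq_len(nrow(labs)), function(i) {
    roi <- atlas@labelVolume == labs$label[i]
    nRoi <- sum(roi)
    if (nRoi == 0L) {
      warning(sprintf("ROI '%s' (label %d) is empty in the label volume",
                      labs$name[i], labs$label[i]))
      return(NULL)
    }
    nSig <- sum(sig & roi)
    if (nSig == 0L) return(NULL)
    data.frame(label = labs$label[i], name = labs$name[i],
               atlas = labs$atlas[i], n_sig = nSig,
               fraction = 100 * nSig / nRoi, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(label = integer(), name = character(),
                       atlas = character(), n_sig = integer(),
                       fraction = numeric(), stringsAsFactors = FALSE)
  rows <- rows[order(-rows$n_sig), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "n_outside") <- sum(sig & atlas@labelVolume == 0L)
  rows
}

#' Peak z statistic and its location
#'
#' Returns the maximum z over the included voxels and its world-space
#' coordinate. Ties are broken by the lexicographically smallest voxel
#' index (recorded in the result).
#'
#' @param stat a [StatMap-class] with at least one included voxel.
#' @return List with `z`, `voxel` (1-based indices) and `world` (mm).
#' @export
peakVoxel <- function(stat) {
  if (stat@nTests == 0L) stop("empty statistic map", call. = FALSE)
  best <- which(stat@zValues == max(stat@zValues))
  if (length(best) > 1L) {
    ord <- order(stat@voxels[best, 1L], stat@voxels[best, 2L],
                 stat@voxels[best, 3L])
    best <- best[ord[1L]]
  }
  vox <- stat@voxels[best, ]
  list(z = stat@zValues[best], voxel = as.integer(vox),
       world = as.numeric(voxelToWorldMat(vox, stat@affine)),
       tied = sum(stat@zValues == max(stat@zValues)) > 1L)
}

#' Voxelwise lesion overlay count
#'
#' Sums the binary masks of a lesion set voxelwise; the maximum value is
#' the maximum lesion overlap in the cohort.
#'
#' @param lesions a [LesionVolumeSet-class].
#' @return Integer 3-D array of overlap counts.
#' @export
overlayCount <- function(lesions) {
  if (length(lesions@masks) == 0L)
    stop("empty lesion set", call. = FALSE)
  Reduce(`+`, lesions@masks)
}
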