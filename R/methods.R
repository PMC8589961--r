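# Generics, accessors and show methods.

#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname accessors
#' @export
setGeneric("lesionMasks", function(x) standardGeneric("lesionMasks"))
#' @rdname accessors
#' @export
setGeneric("volumesCm3", function(x) standardGeneric("volumesCm3"))
#' @rdname accessors
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))
#' @rdname accessors
#' @export
setGeneric("egoCoc", function(x) standardGeneric("egoCoc"))
#' @rdname accessors
#' @export
setGeneric("alloScore", function(x) standardGeneric("alloScore"))
#' @rdname accessors
#' @export
setGeneric("totalHits", function(x) standardGeneric("totalHits"))
#' @rdname accessors
#' @export
setGeneric("impairmentLabels", function(x) standardGeneric("impairmentLabels"))
#' @rdname accessors
#' @export
setGeneric("isExcluded", function(x) standardGeneric("isExcluded"))
#' @rdname accessors
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))
#' @rdname accessors
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))
#' @rdname accessors
#' @export
setGeneric("nTests", function(x) standardGeneric("nTests"))
#' @rdname accessors
#' @export
setGeneric("includedVoxels", function(x) standardGeneric("includedVoxels"))
#' @rdname accessors
#' @export
setGeneric("significantArray", function(x) standardGeneric("significantArray"))
#' @rdname accessors
#' @export
setGeneric("zCut", function(x) standardGeneric("zCut"))
#' @rdname accessors
#' @export
setGeneric("nSignificant", function(x) standardGeneric("nSignificant"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Accessors for package classes
#'
#' Slot accessors for [LesionVolumeSet-class], [BehaviouralScores-class],
#' [StatMap-class] and [ThresholdedMap-class] objects; preferred over
#' direct slot access.
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("patientIds", "LesionVolumeSet", function(x) x@patientIds)
#' @rdname accessors
setMethod("lesionMasks", "LesionVolumeSet", function(x) x@masks)
#' @rdname accessors
setMethod("volumesCm3", "LesionVolumeSet", function(x) x@volumesCm3)
#' @rdname accessors
setMethod("affineMatrix", "LesionVolumeSet", function(x) x@affine)
#' @rdname accessors
setMethod("affineMatrix", "StatMap", function(x) x@affine)
#' @rdname accessors
setMethod("affineMatrix", "ThresholdedMap", function(x) x@affine)
#' @rdname accessors
setMethod("egoCoc", "BehaviouralScores", function(x) x@egoCoc)
#' @rdname accessors
setMethod("alloScore", "BehaviouralScores", function(x) x@alloScore)
#' @rdname accessors
setMethod("totalHits", "BehaviouralScores", function(x) x@totalHits)
#' @rdname accessors
setMethod("impairmentLabels", "BehaviouralScores", function(x) x@labels)
#' @rdname accessors
setMethod("isExcluded", "BehaviouralScores", function(x) x@excluded)
#' @rdname accessors
setMethod("zValues", "StatMap", function(x) x@zValues)
#' @rdname accessors
setMethod("tValues", "StatMap", function(x) x@tValues)
#' @rdname accessors
setMethod("nTests", "StatMap", function(x) x@nTests)
#' @rdname accessors
setMethod("includedVoxels", "StatMap", function(x) x@voxels)
#' @rdname accessors
setMethod("significantArray", "ThresholdedMap", function(x) x@significant)
#' @rdname accessors
setMethod("zCut", "ThresholdedMap", function(x) x@zCut)
#' @rdname accessors
setMethod("nSignificant", "ThresholdedMap", function(x) x@nSignificant)
#' @rdname accessors
setMethod("provenance", "ThresholdedMap", function(x) x@provenance)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      sprintf("%d patients on a %s grid (%s mm voxels)",
              object@nPatients,
              paste(object@gridShape, collapse = "x"),
              paste(object@voxelSizeMm, collapse = "x")), "\n")
  cat(sprintf("  critical region: %d voxels; %d territory seed(s)\n",
              nrow(object@criticalRegion), nrow(object@territorySeeds)))
  cat(sprintf("  lesion radius %g-%g mm; beta=%g gamma=%g noise=%g seed=%d\n",
              object@lesionRadiusRangeMm[1L], object@lesionRadiusRangeMm[2L],
              object@effectBeta, object@volumeGamma, object@noiseSd,
              object@seed))
})

setMethod("show", "CancellationSheet", function(object) {
  st <- object@stimuli
  cat(sprintf("CancellationSheet: %d stimuli on a %gx%g mm page\n",
              nrow(st), object@pageXMax - object@pageXMin,
              object@pageYMax - object@pageYMin))
  tab <- table(factor(st$type,
                      levels = c("complete", "left_gap", "right_gap")))
  cat(sprintf("  complete %d, left_gap %d, right_gap %d; %d marked\n",
              tab[1L], tab[2L], tab[3L], sum(st$marked)))
})

setMethod("show", "BehaviouralScores", function(object) {
  cat(sprintf("BehaviouralScores: hits=%d egoCoC=%.3f egoAsym=%+d alloScore=%.3f alloAsym=%+d\n",
              object@totalHits, object@egoCoc, object@egoAsymmetry,
              object@alloScore, object@alloAsymmetry))
  cat(sprintf("  labels: %s%s\n",
              if (length(object@labels)) paste(object@labels, collapse = ", ")
              else "(none)",
              if (object@excluded) " [EXCLUDED: fewer than 5 hits]" else ""))
})

setMethod("show", "LesionVolumeSet", function(object) {
  n <- length(object@masks)
  cat(sprintf("LesionVolumeSet: %d patient(s)", n))
  if (n) {
    cat(sprintf(" on a %s grid\n  volumes %.2f-%.2f cm^3 (median %.2f)",
                paste(dim(object@masks[[1L]]), collapse = "x"),
                min(object@volumesCm3), max(object@volumesCm3),
                stats::median(object@volumesCm3)))
  }
  cat("\n")
})

setMethod("show", "CohortMatrix", function(object) {
  cat(sprintf("CohortMatrix: %d subjects x %d voxels, direction=%s\n",
              nrow(object@design), ncol(object@design), object@direction))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap: %d voxel(s) tested (min overlap %d, df %d, %d untestable)\n",
              object@nTests, object@minOverlap, object@df,
              object@nUntestable))
  if (object@nTests)
    cat(sprintf("  z range %.3f to %.3f\n",
                min(object@zValues), max(object@zValues)))
})

setMethod("show", "ThresholdedMap", function(object) {
  cat(sprintf("ThresholdedMap: %d significant voxel(s) at z >= %.3f (alpha_corr %.3g)\n",
              object@nSignificant, object@zCut, object@alphaCorrected))
})

setMethod("show", "OverlapReport", function(object) {
  cat(sprintf("OverlapReport: %d common voxel(s); %.2f%% of A%s, %.2f%% of B%s\n",
              object@nCommon,
              object@pctOfA, if (object@undefinedA) " (A empty)" else "",
              object@pctOfB, if (object@undefinedB) " (B empty)" else ""))
})

setMethod("show", "AtlasLabels", function(object) {
  cat(sprintf("AtlasLabels: %d ROI(s) on a %s grid\n",
              nrow(object@names),
              paste(dim(object@labelVolume), collapse = "x")))
})
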