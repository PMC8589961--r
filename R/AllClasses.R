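#' @import methods
NULL

#' Configuration for a synthetic lesion-behaviour cohort
#'
#' Bundles the geometry of the common voxel grid, the lesion generator
#' settings, and the linear lesion-deficit model used to produce continuous
#' severity scores with known ground truth.
#'
#' @slot gridShape integer(3), voxels per axis (x, y, z).
#' @slot voxelSizeMm numeric(3), voxel edge lengths in mm.
#' @slot nPatients number of patients to simulate.
#' @slot criticalRegion integer matrix (n x 3) of 1-based voxel indices; the
#'   implanted ground-truth correlate whose damage drives the deficit.
#' @slot territorySeeds numeric matrix (k x 3) of voxel-coordinate centroids
#'   from which lesions are grown (vascular-territory stand-ins).
#' @slot territoryWeights numeric(k), sampling weight of each territory.
#' @slot lesionRadiusRangeMm numeric(2), min/max lesion radius in mm.
#' @slot effectBeta severity gained per unit lesion load (fraction of the
#'   critical region destroyed, in [0, 1]).
#' @slot volumeGamma nuisance severity per cm^3 of total lesion volume.
#' @slot noiseSd standard deviation of additive Gaussian noise on the score.
#' @slot anisotropyJitter relative spread of the per-axis ellipsoid scale
#'   factors (0 gives exactly spherical lesions).
#' @slot seed integer RNG seed; identical configs reproduce bit-identical
#'   cohorts.
#' @seealso [simulationConfig()], [simulateLesionCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    gridShape = "integer",
    voxelSizeMm = "numeric",
    nPatients = "integer",
    criticalRegion = "matrix",
    territorySeeds = "matrix",
    territoryWeights = "numeric",
    lesionRadiusRangeMm = "numeric",
    effectBeta = "numeric",
    volumeGamma = "numeric",
    noiseSd = "numeric",
    anisotropyJitter = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxelSizeMm must be 3 positive reals")
  if (object@nPatients < 0L)
    msg <- c(msg, "nPatients must be nonnegative")
  if (nrow(object@criticalRegion) == 0L)
    msg <- c(msg, "criticalRegion must be nonempty")
  if (ncol(object@criticalRegion) != 3L)
    msg <- c(msg, "criticalRegion must have 3 columns (voxel indices)")
  else {
    inGrid <- object@criticalRegion >= 1L &
      object@criticalRegion <= matrix(object@gridShape,
        nrow(object@criticalRegion), 3L, byrow = TRUE)
    if (!all(inGrid))
      msg <- c(msg, "criticalRegion voxels must lie inside gridShape")
  }
  if (ncol(object@territorySeeds) != 3L || nrow(object@territorySeeds) == 0L)
    msg <- c(msg, "territorySeeds must be a nonempty k x 3 matrix")
  if (length(object@territoryWeights) != nrow(object@territorySeeds) ||
      any(object@territoryWeights < 0) || sum(object@territoryWeights) <= 0)
    msg <- c(msg, "territoryWeights must be nonnegative, one per seed, not all zero")
  if (length(object@lesionRadiusRangeMm) != 2L ||
      any(object@lesionRadiusRangeMm <= 0) ||
      object@lesionRadiusRangeMm[1L] > object@lesionRadiusRangeMm[2L])
    msg <- c(msg, "lesionRadiusRangeMm must be positive with min <= max")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be nonnegative")
  if (object@anisotropyJitter < 0 || object@anisotropyJitter >= 1)
    msg <- c(msg, "anisotropyJitter must be in [0, 1)")
  # the smallest admissible blob must fit in the grid
  if (any(object@lesionRadiusRangeMm[1L] >
          object@gridShape * object@voxelSizeMm))
    msg <- c(msg, "grid too small to contain a blob of the minimum radius")
  if (length(msg)) msg else TRUE
})

#' One patient's cancellation sheet
#'
#' Stimulus layout and responses for a Hearts-type cancellation task: 150
#' heart outlines (50 complete targets, 50 left-gap and 50 right-gap
#' distractors) scattered over a landscape A4 page. Partial sheets are
#' representable; [validateStandardSheet()] checks the 50/50/50 layout.
#'
#' @slot stimuli data.frame with columns `x` (mm along the left-right page
#'   axis), `y` (mm), `type` (one of `"complete"`, `"left_gap"`,
#'   `"right_gap"`) and `marked` (logical).
#' @slot pageXMin,pageXMax page extent along x in mm; the centre-of-
#'   cancellation weights are normalised by half this width.
#' @slot pageYMin,pageYMax page extent along y in mm.
#' @seealso [simulateSheet()], [scoreSheet()], [readSheet()]
#' @export
setClass("CancellationSheet",
  representation(
    stimuli = "data.frame",
    pageXMin = "numeric",
    pageXMax = "numeric",
    pageYMin = "numeric",
    pageYMax = "numeric"
  )
)

setValidity("CancellationSheet", function(object) {
  msg <- character()
  st <- object@stimuli
  need <- c("x", "y", "type", "marked")
  if (!all(need %in% names(st)))
    return(sprintf("stimuli must have columns %s", paste(need, collapse = ", ")))
  if (!all(st$type %in% c("complete", "left_gap", "right_gap")))
    msg <- c(msg, "stim types must be complete, left_gap or right_gap")
  if (!is.logical(st$marked))
    msg <- c(msg, "marked must be logical")
  if (object@pageXMin >= object@pageXMax)
    msg <- c(msg, "pageXMin must be < pageXMax")
  if (nrow(st) && (any(st$x < object@pageXMin) || any(st$x > object@pageXMax)))
    msg <- c(msg, "stimulus x positions must lie within the page")
  if (length(msg)) msg else TRUE
})

#' Behavioural scores for one cancellation sheet
#'
#' Continuous egocentric/allocentric severities, raw count asymmetries, the
#' categorical impairment labels derived from them, and the exclusion flag
#' for unscorable performances (fewer than 5 hits).
#'
#' @slot totalHits marked complete targets.
#' @slot egoCoc centre of cancellation in [-1, 1]; positive means marks
#'   concentrated rightward, i.e. LEFT egocentric neglect.
#' @slot egoAsymmetry right-half hits minus left-half hits.
#' @slot alloScore signed lateralised false-positive proportion; positive
#'   means left-gap false positives dominate, i.e. LEFT allocentric neglect.
#' @slot alloAsymmetry left-gap false positives minus right-gap false
#'   positives.
#' @slot labels subset of `c("left_ego","right_ego","left_allo","right_allo")`.
#' @slot excluded TRUE when totalHits < 5 (scores unreliable).
#' @seealso [scoreSheet()], [classifyImpairment()]
#' @export
setClass("BehaviouralScores",
  representation(
    totalHits = "integer",
    egoCoc = "numeric",
    egoAsymmetry = "integer",
    alloScore = "numeric",
    alloAsymmetry = "integer",
    labels = "character",
    excluded = "logical"
  )
)

setValidity("BehaviouralScores", function(object) {
  msg <- character()
  if (!is.na(object@egoCoc) && abs(object@egoCoc) > 1 + 1e-12)
    msg <- c(msg, "|egoCoc| must be <= 1")
  if (!is.na(object@alloScore) && abs(object@alloScore) > 1 + 1e-12)
    msg <- c(msg, "|alloScore| must be <= 1")
  if (!all(object@labels %in%
           c("left_ego", "right_ego", "left_allo", "right_allo")))
    msg <- c(msg, "unknown impairment label")
  if (object@excluded != (object@totalHits < 5L))
    msg <- c(msg, "excluded must equal (totalHits < 5)")
  if (length(msg)) msg else TRUE
})

#' A set of aligned binary lesion masks
#'
#' Per-patient binary lesion masks on one shared voxel grid, with the
#' voxel-to-world affine (mm, right-handed, world x = left to right) and
#' per-patient lesion volumes in cm^3.
#'
#' @slot patientIds character patient identifiers.
#' @slot masks list of 3-D 0/1 arrays, all with the same dimensions.
#' @slot affine 4 x 4 voxel-to-world matrix (0-based voxel indices, mm).
#' @slot voxelSizeMm numeric(3) voxel edge lengths in mm.
#' @slot volumesCm3 per-patient lesion volume in cm^3.
#' @seealso [readMaskSet()], [simulateLesionCohort()], [lesionVolumeCm3()]
#' @export
setClass("LesionVolumeSet",
  representation(
    patientIds = "character",
    masks = "list",
    affine = "matrix",
    voxelSizeMm = "numeric",
    volumesCm3 = "numeric"
  )
)

setValidity("LesionVolumeSet", function(object) {
  msg <- character()
  n <- length(object@masks)
  if (length(object@patientIds) != n || length(object@volumesCm3) != n)
    msg <- c(msg, "patientIds, masks and volumesCm3 must have equal length")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be 4 x 4")
  if (n > 0L) {
    d <- dim(object@masks[[1L]])
    if (length(d) != 3L)
      msg <- c(msg, "masks must be 3-D arrays")
    else if (!all(vapply(object@masks, function(m) identical(dim(m), d), TRUE)))
      msg <- c(msg, "all masks must share one grid shape")
    if (!all(vapply(object@masks, function(m) all(m %in% c(0, 1)), TRUE)))
      msg <- c(msg, "mask values must be 0 or 1")
    vv <- prod(object@voxelSizeMm) / 1000
    expect <- vapply(object@masks, function(m) sum(m) * vv, 0)
    if (any(abs(expect - object@volumesCm3) > 1e-8 * pmax(1, abs(expect))))
      msg <- c(msg, "volumesCm3 must equal voxel count x voxel volume / 1000")
  }
  if (length(msg)) msg else TRUE
})

#' Subjects-by-voxels analysis matrix for one VLSM run
#'
#' The mass-univariate design: one binary column per voxel of the grid
#' (lesioned / intact), the continuous severity score per subject, the
#' lesion-volume nuisance covariate, and the hypothesised direction of the
#' one-tailed test.
#'
#' @slot design subjects x voxels binary matrix (column-major voxel order).
#' @slot voxelIndex integer matrix (voxels x 3) mapping design columns to
#'   1-based grid coordinates.
#' @slot scores per-subject continuous severity (centre of cancellation or
#'   allocentric proportional score).
#' @slot volumesCm3 per-subject total lesion volume in cm^3.
#' @slot direction `"positive"` when lesion is hypothesised to raise the
#'   score, `"negative"` when it is hypothesised to lower it.
#' @slot gridShape integer(3) dimensions of the underlying grid.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @seealso [cohortMatrix()], [runVlsm()]
#' @export
setClass("CohortMatrix",
  representation(
    design = "matrix",
    voxelIndex = "matrix",
    scores = "numeric",
    volumesCm3 = "numeric",
    direction = "character",
    gridShape = "integer",
    affine = "matrix"
  )
)

setValidity("CohortMatrix", function(object) {
  msg <- character()
  if (!all(object@design %in% c(0, 1)))
    msg <- c(msg, "design must be binary")
  if (nrow(object@design) != length(object@scores) ||
      nrow(object@design) != length(object@volumesCm3))
    msg <- c(msg, "design rows must match scores and volumes length")
  if (ncol(object@design) != nrow(object@voxelIndex))
    msg <- c(msg, "voxelIndex must map every design column")
  if (!object@direction %in% c("positive", "negative"))
    msg <- c(msg, "direction must be 'positive' or 'negative'")
  if (length(msg)) msg else TRUE
})

#' Voxelwise statistic map
#'
#' Per-voxel pooled-variance t statistics and their one-tailed z equivalents
#' for the voxels passing the minimum-overlap filter.
#'
#' @slot tValues,zValues per-included-voxel statistics; z is signed in the
#'   direction of the hypothesised lesion-deficit association.
#' @slot df pooled-t degrees of freedom (n subjects - 2).
#' @slot voxels integer matrix (nTests x 3) of included 1-based voxel
#'   coordinates.
#' @slot nTests number of voxels tested (the Bonferroni family size).
#' @slot minOverlap the overlap filter that defined the family.
#' @slot nUntestable voxels dropped because one group had < 2 members.
#' @slot gridShape,affine grid geometry.
#' @seealso [runVlsm()], [peakVoxel()]
#' @export
setClass("StatMap",
  representation(
    tValues = "numeric",
    zValues = "numeric",
    df = "integer",
    voxels = "matrix",
    nTests = "integer",
    minOverlap = "integer",
    nUntestable = "integer",
    gridShape = "integer",
    affine = "matrix"
  )
)

setValidity("StatMap", function(object) {
  msg <- character()
  if (length(object@tValues) != length(object@zValues))
    msg <- c(msg, "tValues and zValues must have equal length")
  if (nrow(object@voxels) != length(object@tValues))
    msg <- c(msg, "voxels must map every statistic")
  if (object@nTests != nrow(object@voxels))
    msg <- c(msg, "nTests must equal the number of included voxels")
  if (length(msg)) msg else TRUE
})

#' Thresholded significance map
#'
#' Binary map of voxels surviving the Bonferroni z threshold, with the
#' threshold itself and run provenance.
#'
#' @slot significant 3-D 0/1 array on the analysis grid.
#' @slot zCut the one-tailed normal quantile applied.
#' @slot alphaCorrected the Bonferroni-corrected alpha.
#' @slot nSignificant nonzero voxel count of `significant`.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @slot provenance named list (n_tests, df, direction, mirroring notes, ...).
#' @seealso [runVlsm()], [mirrorHomologue()], [mapOverlap()]
#' @export
setClass("ThresholdedMap",
  representation(
    significant = "array",
    zCut = "numeric",
    alphaCorrected = "numeric",
    nSignificant = "integer",
    affine = "matrix",
    provenance = "list"
  )
)

setValidity("ThresholdedMap", function(object) {
  msg <- character()
  if (!all(object@significant %in% c(0, 1)))
    msg <- c(msg, "significant must be binary")
  if (object@nSignificant != sum(object@significant != 0))
    msg <- c(msg, "nSignificant must equal the nonzero count of significant")
  if (length(msg)) msg else TRUE
})

#' Integer-label atlas on the analysis grid
#'
#' A winner-take-all anatomical parcellation: an integer label volume plus a
#' lookup table of region names. Label 0 is background.
#'
#' @slot labelVolume 3-D integer array.
#' @slot names data.frame with columns `label`, `name`, `atlas`.
#' @seealso [atlasFractions()]
#' @export
setClass("AtlasLabels",
  representation(labelVolume = "array", names = "data.frame")
)

setValidity("AtlasLabels", function(object) {
  msg <- character()
  need <- c("label", "name", "atlas")
  if (!all(need %in% names(object@names)))
    return("names must have columns label, name, atlas")
  labs <- setdiff(unique(as.vector(object@labelVolume)), 0L)
  if (!all(labs %in% object@names$label))
    msg <- c(msg, "every nonzero label must be present in the names table")
  if (length(msg)) msg else TRUE
})

#' Overlap between two thresholded maps
#'
#' @slot nCommon voxels significant in both maps.
#' @slot pctOfA,pctOfB 100 * nCommon / |A| (resp. |B|); 0 with the
#'   corresponding `undefined` flag when the map is empty.
#' @slot undefinedA,undefinedB TRUE when the denominator map was empty.
#' @seealso [mapOverlap()]
#' @export
setClass("OverlapReport",
  representation(
    nCommon = "integer",
    pctOfA = "numeric",
    pctOfB = "numeric",
    undefinedA = "logical",
    undefinedB = "logical"
  )
)

setValidity("OverlapReport", function(object) {
  if (object@pctOfA < 0 || object@pctOfA > 100 ||
      object@pctOfB < 0 || object@pctOfB > 100)
    "percentages must lie in [0, 100]" else TRUE
})
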