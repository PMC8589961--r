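# Mass-univariate lesion-behaviour statistics: minimum-overlap filter,
# lesion-volume residualization, voxelwise one-tailed pooled-variance
# t-tests, and Bonferroni z-thresholding.

#' Assemble the subjects-by-voxels cohort matrix
#'
#' Flattens a set of aligned binary masks into the VLSM design matrix and
#' attaches the behavioural scores, the lesion-volume covariate and the
#' hypothesised test direction.
#'
#' @param lesions a [LesionVolumeSet-class].
#' @param scores per-subject continuous severity, same order as patients.
#' @param direction `"positive"` when lesion damage is hypothesised to
#'   raise the score (e.g. centre of cancellation in a left-neglect
#'   analysis), `"negative"` when it is hypothesised to lower it.
#' @return A [CohortMatrix-class].
#' @export
cohortMatrix <- function(lesions, scores, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  validObject(lesions)
  if (length(scores) != length(lesions@masks))
    stop("scores must have one entry per patient", call. = FALSE)
  g <- if (length(lesions@masks)) dim(lesions@masks[[1L]]) else c(0L, 0L, 0L)
  design <- do.call(rbind, lapply(lesions@masks, as.vector))
  if (is.null(design)) design <- matrix(0, 0L, prod(g))
  nv <- prod(g)
  voxelIndex <- if (nv > 0L) linearVox(seq_len(nv), as.integer(g))
                else matrix(integer(), 0L, 3L)
  new("CohortMatrix",
    design = design, voxelIndex = voxelIndex,
    scores = as.numeric(scores), volumesCm3 = lesions@volumesCm3,
    direction = direction, gridShape = as.integer(g),
    affine = lesions@affine
  )
}

#' Minimum-overlap voxel filter
#'
#' Returns the design columns lesioned in at least `minOverlap` patients;
#' only these voxels enter the statistical family. The inequality is
#' inclusive: a voxel lesioned in exactly `minOverlap` patients is tested.
#'
#' @param design subjects x voxels binary matrix.
#' @param minOverlap minimum number of lesioned patients (default 10).
#' @return Integer vector of included column indices.
#' @export
overlapFilter <- function(design, minOverlap = 10L) {
  which(colSums(design) >= minOverlap)
}

#' Residualize scores on lesion volume
#'
#' Controls for lesion volume by ordinary least squares: fits
#' `score ~ 1 + volume` and returns the residuals, which are exactly
#' orthogonal to the volume vector and sum to zero. With a degenerate
#' (constant) volume covariate the scores are mean-centred instead and a
#' `degenerate` attribute is set with a warning.
#'
#' @param scores per-subject severity.
#' @param volumesCm3 per-subject lesion volume.
#' @return Numeric residuals, with attribute `degenerate` (logical).
#' @export
residualizeScores <- function(scores, volumesCm3) {
  if (length(scores) != length(volumesCm3))
    stop("scores and volumesCm3 must have the same length", call. = FALSE)
  if (length(scores) < 3L)
    stop("need at least 3 subjects to residualize", call. = FALSE)
  if (stats::var(volumesCm3) == 0) {
    warning("lesion volumes are constant; returning mean-centred scores")
    res <- scores - mean(scores)
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  fit <- stats::lm.fit(cbind(1, volumesCm3), scores)
  res <- as.numeric(fit$residuals)
  attr(res, "degenerate") <- FALSE
  res
}

#' Voxelwise one-tailed pooled-variance t-tests
#'
#' For every design column, compares the (volume-adjusted) scores of
#' lesioned versus intact subjects with a pooled-variance two-sample t
#' statistic, `df = n1 + n2 - 2`. The statistic is oriented so that the
#' hypothesised lesion-deficit association is positive: for
#' `direction = "negative"` the scores are negated first. The one-tailed p
#' comes from the exact t upper tail and is mapped to a signed z through
#' the standard-normal quantile (computed on the log scale, so extreme
#' statistics keep full precision).
#'
#' Voxels where either group has fewer than 2 members are untestable and
#' return NA (they are dropped and counted by [runVlsm()]). Zero pooled
#' variance with equal group means yields t = 0.
#'
#' @param design subjects x voxels binary matrix (already overlap-filtered).
#' @param scores adjusted per-subject scores.
#' @param direction `"positive"` or `"negative"`.
#' @return List with vectors `t`, `z` (one per column) and scalar `df`.
#' @export
voxelTTest <- function(design, scores, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  s <- if (direction == "negative") -as.numeric(scores) else as.numeric(scores)
  n <- length(s)
  n1 <- colSums(design)                     # lesioned
  n2 <- n - n1                              # intact
  sum1 <- as.numeric(crossprod(design, s))
  sumsq1 <- as.numeric(crossprod(design, s^2))
  m1 <- sum1 / n1
  m2 <- (sum(s) - sum1) / n2
  ss1 <- sumsq1 - n1 * m1^2
  ss2 <- (sum(s^2) - sumsq1) - n2 * m2^2
  df <- n - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[sp2 <= 0 & abs(m1 - m2) < 1e-300] <- 0  # zero variance, equal means
  t[n1 < 2 | n2 < 2] <- NA_real_            # untestable
  # exact t tail -> normal quantile, via log probabilities
  logp <- stats::pt(t, df = df, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  list(t = t, z = z, df = as.integer(df))
}

#' Bonferroni family-wise threshold
#'
#' Divides the family-wise alpha by the number of tests and converts the
#' corrected alpha to the one-tailed standard-normal cut-off applied to the
#' z map. With 589,216 tests at alpha 0.05 this gives corrected alpha
#' 8.49e-8 and z-cut 5.23.
#'
#' @param alphaFamily family-wise alpha (default 0.05).
#' @param nTests number of voxels tested.
#' @return List with `alphaCorrected` and `zCut`.
#' @examples
#' bonferroniThreshold(0.05, 589216)
#' @export
bonferroniThreshold <- function(alphaFamily = 0.05, nTests) {
  if (nTests < 1L) stop("nTests must be at least 1 (nothing to test)",
                        call. = FALSE)
  if (alphaFamily <= 0 || alphaFamily >= 1)
    stop("alphaFamily must lie in (0, 1)", call. = FALSE)
  alphaCorrected <- alphaFamily / nTests
  list(alphaCorrected = alphaCorrected,
       zCut = stats::qnorm(alphaCorrected, lower.tail = FALSE))
}

#' Run a full voxel-lesion symptom mapping analysis
#'
#' The complete mass-univariate pipeline: minimum-overlap filter,
#' residualization of the severity score on lesion volume, a pooled-
#' variance one-tailed t-test at every included voxel, exact-t-to-z
#' conversion, and Bonferroni thresholding of the z map at
#' `alphaFamily / nTests`. Untestable voxels (one group with fewer than 2
#' members) are dropped and counted. With zero included voxels the result
#' is an empty map with `nTests = 0` recorded, not an error.
#'
#' @param cohort a [CohortMatrix-class].
#' @param alphaFamily family-wise alpha (default 0.05).
#' @param minOverlap minimum lesioned-patient count per voxel (default 10).
#' @return List with elements `stat` (a [StatMap-class]), `thresholded`
#'   (a [ThresholdedMap-class]) and `manifest` (named list: n_subjects,
#'   n_tests, n_untestable, df, alpha_corrected, z_cut, n_significant,
#'   direction, min_overlap, degenerate_volume).
#' @examples
#' cfg <- simulationConfig(gridShape = c(12, 12, 8), nPatients = 30,
#'                         lesionRadiusRangeMm = c(5, 9), seed = 2)
#' cohort <- simulateLesionCohort(cfg)
#' sev <- simulateBehaviour(cohort$truth$load, cohort$truth$volume_cm3, cfg)
#' res <- runVlsm(cohortMatrix(cohort$lesions, sev), minOverlap = 5)
#' res$manifest$n_tests
#' @export
runVlsm <- function(cohort, alphaFamily = 0.05, minOverlap = 10L) {
  validObject(cohort)
  included <- overlapFilter(cohort@design, minOverlap)
  g <- cohort@gridShape
  emptyManifest <- function(nTests) list(
    n_subjects = nrow(cohort@design), n_tests = nTests, n_untestable = 0L,
    df = max(nrow(cohort@design) - 2L, 0L), alpha_corrected = NA_real_,
    z_cut = NA_real_, n_significant = 0L, direction = cohort@direction,
    min_overlap = as.integer(minOverlap), degenerate_volume = FALSE
  )
  if (length(included) == 0L) {
    stat <- new("StatMap",
      tValues = numeric(), zValues = numeric(),
      df = max(nrow(cohort@design) - 2L, 0L),
      voxels = matrix(integer(), 0L, 3L), nTests = 0L,
      minOverlap = as.integer(minOverlap), nUntestable = 0L,
      gridShape = g, affine = cohort@affine
    )
    thr <- new("ThresholdedMap",
      significant = array(0, dim = g), zCut = NA_real_,
      alphaCorrected = NA_real_, nSignificant = 0L,
      affine = cohort@affine, provenance = emptyManifest(0L)
    )
    return(list(stat = stat, thresholded = thr, manifest = emptyManifest(0L)))
  }

  adj <- residualizeScores(cohort@scores, cohort@volumesCm3)
  tt <- voxelTTest(cohort@design[, included, drop = FALSE], adj,
                   cohort@direction)
  testable <- !is.na(tt$t)
  nUntestable <- sum(!testable)
  included <- included[testable]
  tv <- tt$t[testable]
  zv <- tt$z[testable]
  nTests <- length(included)
  voxels <- cohort@voxelIndex[included, , drop = FALSE]

  bon <- bonferroniThreshold(alphaFamily, nTests)
  sigArr <- array(0, dim = g)
  sigIdx <- included[zv >= bon$zCut]
  sigArr[sigIdx] <- 1

  manifest <- list(
    n_subjects = nrow(cohort@design),
    n_tests = nTests,
    n_untestable = as.integer(nUntestable),
    df = tt$df,
    alpha_corrected = bon$alphaCorrected,
    z_cut = bon$zCut,
    n_significant = length(sigIdx),
    direction = cohort@direction,
    min_overlap = as.integer(minOverlap),
    degenerate_volume = isTRUE(attr(adj, "degenerate"))
  )
  stat <- new("StatMap",
    tValues = tv, zValues = zv, df = tt$df,
    voxels = matrix(as.integer(voxels), ncol = 3L),
    nTests = as.integer(nTests), minOverlap = as.integer(minOverlap),
    nUntestable = as.integer(nUntestable),
    gridShape = g, affine = cohort@affine
  )
  thr <- new("ThresholdedMap",
    significant = sigArr, zCut = bon$zCut,
    alphaCorrected = bon$alphaCorrected,
    nSignificant = length(sigIdx),
    affine = cohort@affine, provenance = manifest
  )
  list(stat = stat, thresholded = thr, manifest = manifest)
}
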