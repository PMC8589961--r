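# Hearts-cancellation scoring: continuous egocentric (centre of
# cancellation) and allocentric (lateralised false-positive proportion)
# severities, raw count asymmetries, and categorical impairment labels.

# Normative impairment thresholds on the raw count asymmetries; strict
# inequalities, so values at exactly +/- the threshold are unimpaired.
EGO_ASYM_THRESHOLD <- 3L
ALLO_ASYM_THRESHOLD <- 1L
MIN_TOTAL_HITS <- 5L

#' Centre of cancellation
#'
#' Assigns each complete target a weight linear in its left-right page
#' position, `w = (x - xCentre) / (half page width)` in [-1, 1], and
#' returns the mean weight of the MARKED complete targets. Positive values
#' mean marks concentrated rightward, i.e. left egocentric neglect.
#'
#' @param sheet a [CancellationSheet-class].
#' @return The centre of cancellation, a real in [-1, 1].
#' @examples
#' coc <- centerOfCancellation(simulateSheet("left_ego", 1, seed = 3))
#' stopifnot(coc > 0)
#' @export
centerOfCancellation <- function(sheet) {
  st <- sheet@stimuli
  hit <- st$type == "complete" & st$marked
  if (!any(hit))
    stop("centre of cancellation undefined: no marked complete targets ",
         "(treat the patient as excluded)", call. = FALSE)
  mean(cocWeights(st$x[hit], sheet))
}

cocWeights <- function(x, sheet) {
  centre <- (sheet@pageXMin + sheet@pageXMax) / 2
  (x - centre) / ((sheet@pageXMax - sheet@pageXMin) / 2)
}

#' Allocentric proportional score
#'
#' The number of consistently-lateralised false-positive responses divided
#' by the number of reported targets:
#' `(marked left-gap - marked right-gap) / (all marked stimuli)`.
#' Positive values mean left-gap false positives dominate, i.e. left
#' allocentric neglect. Bounded in [-1, 1].
#'
#' @param sheet a [CancellationSheet-class].
#' @return The signed allocentric score.
#' @export
allocentricScore <- function(sheet) {
  st <- sheet@stimuli
  total <- sum(st$marked)
  if (total == 0L)
    stop("allocentric score undefined: no marked stimuli", call. = FALSE)
  fpL <- sum(st$marked & st$type == "left_gap")
  fpR <- sum(st$marked & st$type == "right_gap")
  (fpL - fpR) / total
}

#' Classify impairment from raw count asymmetries
#'
#' Applies the normative thresholds to the raw asymmetries: egocentric
#' asymmetry greater than 3 flags `left_ego`, less than -3 flags
#' `right_ego`; allocentric asymmetry greater than 1 flags `left_allo`,
#' less than -1 flags `right_allo`. All inequalities are strict, so
#' boundary values are unimpaired. Egocentric and allocentric labels can
#' co-occur.
#'
#' @param egoAsymmetry right-half hits minus left-half hits.
#' @param alloAsymmetry left-gap false positives minus right-gap false
#'   positives.
#' @return Character vector of impairment labels (possibly empty).
#' @examples
#' classifyImpairment(4, 0)    # "left_ego"
#' classifyImpairment(3, 1)    # character(0): boundaries are unimpaired
#' classifyImpairment(-5, -2)  # "right_ego", "right_allo"
#' @export
classifyImpairment <- function(egoAsymmetry, alloAsymmetry) {
  labels <- character()
  if (egoAsymmetry > EGO_ASYM_THRESHOLD) labels <- c(labels, "left_ego")
  if (egoAsymmetry < -EGO_ASYM_THRESHOLD) labels <- c(labels, "right_ego")
  if (alloAsymmetry > ALLO_ASYM_THRESHOLD) labels <- c(labels, "left_allo")
  if (alloAsymmetry < -ALLO_ASYM_THRESHOLD) labels <- c(labels, "right_allo")
  labels
}

#' Score a cancellation sheet
#'
#' Computes all behavioural measures for one sheet: total hits, centre of
#' cancellation, egocentric count asymmetry (right-half hits minus
#' left-half hits; targets exactly at the page centre count toward
#' neither half), allocentric proportional score, allocentric count
#' asymmetry, impairment labels, and the exclusion flag. Sheets with fewer
#' than 5 hits are flagged excluded and receive no labels; with zero marked
#' stimuli the continuous scores are NA.
#'
#' @param sheet a [CancellationSheet-class].
#' @return A [BehaviouralScores-class].
#' @examples
#' scoreSheet(simulateSheet("none", seed = 1))
#' @export
scoreSheet <- function(sheet) {
  validObject(sheet)
  st <- sheet@stimuli
  hit <- st$type == "complete" & st$marked
  totalHits <- sum(hit)
  centre <- (sheet@pageXMin + sheet@pageXMax) / 2

  egoCoc <- if (totalHits > 0L) centerOfCancellation(sheet) else NA_real_
  egoAsym <- sum(hit & st$x > centre) - sum(hit & st$x < centre)
  alloScore <- if (sum(st$marked) > 0L) allocentricScore(sheet) else NA_real_
  alloAsym <- sum(st$marked & st$type == "left_gap") -
    sum(st$marked & st$type == "right_gap")

  excluded <- totalHits < MIN_TOTAL_HITS
  labels <- if (excluded) character() else
    classifyImpairment(egoAsym, alloAsym)

  new("BehaviouralScores",
    totalHits = as.integer(totalHits),
    egoCoc = egoCoc,
    egoAsymmetry = as.integer(egoAsym),
    alloScore = alloScore,
    alloAsymmetry = as.integer(alloAsym),
    labels = labels,
    excluded = excluded
  )
}

#' Check a sheet against the standard Hearts layout
#'
#' The standard sheet carries exactly 50 stimuli of each type. Partial
#' sheets are still scorable; this validator reports deviations.
#'
#' @param sheet a [CancellationSheet-class].
#' @return TRUE invisibly, or a character vector of problems.
#' @export
validateStandardSheet <- function(sheet) {
  counts <- table(factor(sheet@stimuli$type,
                         levels = c("complete", "left_gap", "right_gap")))
  if (all(counts == N_PER_TYPE)) return(invisible(TRUE))
  sprintf("expected 50 of each stimulus type, got %s",
          paste(names(counts), counts, sep = "=", collapse = ", "))
}
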