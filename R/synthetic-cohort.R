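# Synthetic lesion-behaviour cohorts with implanted ground truth.
#
# Lesions are grown as thresholded ellipsoidal distance fields seeded from
# vascular-territory centroids; behaviour follows a linear lesion-deficit
# model (severity = beta * critical-region load + gamma * volume + noise).
# Cancellation sheets are simulated from a small set of lateralised
# phenotypes with a logistic severity-to-probability mapping in page
# position.

#' Build a simulation configuration
#'
#' Constructs a validated [SimulationConfig-class]. Defaults describe a
#' modest cohort on a 40 x 40 x 30 grid of 2 mm voxels: four territory
#' seeds (two per hemisphere), lesion radii of 5-20 mm giving volumes on
#' the cm^3 scale typical of acute stroke, a spherical critical region of
#' 6 mm radius in the right temporo-parietal quadrant, and a weak
#' lesion-volume nuisance effect.
#'
#' @param gridShape integer(3), voxels per axis.
#' @param voxelSizeMm numeric(3), voxel size in mm.
#' @param nPatients number of patients.
#' @param criticalRegion n x 3 matrix of 1-based voxel indices, or NULL for
#'   the default sphere.
#' @param territorySeeds k x 3 matrix of voxel-coordinate centroids, or NULL
#'   for defaults.
#' @param territoryWeights sampling weights, one per seed.
#' @param lesionRadiusRangeMm numeric(2), min/max blob radius in mm.
#' @param effectBeta severity per unit critical-region load (load in [0,1]).
#' @param volumeGamma severity per cm^3 of total lesion volume (nuisance).
#' @param noiseSd additive Gaussian noise sd.
#' @param anisotropyJitter relative spread of per-axis ellipsoid scales;
#'   0 gives spheres.
#' @param seed RNG seed.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nPatients = 4, seed = 1)
#' cohort <- simulateLesionCohort(cfg)
#' cohort$truth
#' @export
simulationConfig <- function(gridShape = c(40L, 40L, 30L),
                             voxelSizeMm = c(2, 2, 2),
                             nPatients = 40L,
                             criticalRegion = NULL,
                             territorySeeds = NULL,
                             territoryWeights = NULL,
                             lesionRadiusRangeMm = c(5, 20),
                             effectBeta = 1,
                             volumeGamma = 0.01,
                             noiseSd = 0.1,
                             anisotropyJitter = 0.1,
                             seed = 1L) {
  gridShape <- as.integer(gridShape)
  if (is.null(territorySeeds)) {
    # two anterior/posterior seeds per hemisphere, placed fractionally
    fr <- rbind(
      c(0.30, 0.45, 0.50), c(0.70, 0.45, 0.50),
      c(0.30, 0.70, 0.45), c(0.70, 0.70, 0.45)
    )
    territorySeeds <- sweep(fr, 2L, gridShape, "*")
  }
  territorySeeds <- matrix(as.numeric(territorySeeds), ncol = 3L)
  if (is.null(territoryWeights))
    territoryWeights <- rep(1, nrow(territorySeeds))
  if (is.null(criticalRegion))
    criticalRegion <- sphereRegion(
      centreVox = gridShape * c(0.70, 0.45, 0.50),
      radiusMm = 6, gridShape = gridShape, voxelSizeMm = voxelSizeMm
    )
  new("SimulationConfig",
    gridShape = gridShape,
    voxelSizeMm = as.numeric(voxelSizeMm),
    nPatients = as.integer(nPatients),
    criticalRegion = matrix(as.integer(round(criticalRegion)), ncol = 3L),
    territorySeeds = territorySeeds,
    territoryWeights = as.numeric(territoryWeights),
    lesionRadiusRangeMm = as.numeric(lesionRadiusRangeMm),
    effectBeta = as.numeric(effectBeta),
    volumeGamma = as.numeric(volumeGamma),
    noiseSd = as.numeric(noiseSd),
    anisotropyJitter = as.numeric(anisotropyJitter),
    seed = as.integer(seed)
  )
}

#' Voxel indices of a sphere on a grid
#'
#' All voxels whose centres lie within `radiusMm` of the given voxel-space
#' centre. Used to define critical regions and toy atlas ROIs.
#'
#' @param centreVox numeric(3) 1-based voxel coordinate of the centre.
#' @param radiusMm radius in mm.
#' @param gridShape integer(3) grid dimensions.
#' @param voxelSizeMm numeric(3) voxel size in mm.
#' @return Integer matrix (n x 3) of 1-based voxel indices.
#' @export
sphereRegion <- function(centreVox, radiusMm, gridShape, voxelSizeMm) {
  d2 <- distanceField2(centreVox, rep(1, 3), gridShape, voxelSizeMm)
  which(d2 <= radiusMm^2, arr.ind = TRUE)
}

# Squared anisotropy-scaled distance (mm^2) from a voxel-space centre, over
# the whole grid, as a 3-D array. Separable: dx^2/ax^2 + dy^2/ay^2 + ...
distanceField2 <- function(centreVox, axisScale, gridShape, voxelSizeMm) {
  ax <- lapply(1:3, function(a) {
    ((seq_len(gridShape[a]) - centreVox[a]) * voxelSizeMm[a] / axisScale[a])^2
  })
  outer(outer(ax[[1L]], ax[[2L]], "+"), ax[[3L]], "+")
}

#' Simulate a cohort of binary lesion masks
#'
#' Each lesion is a contiguous ellipsoidal blob: a territory seed is sampled
#' by weight, its centroid jittered and snapped to a voxel centre, a radius
#' drawn uniformly from `lesionRadiusRangeMm`, and per-axis scale factors
#' drawn within `1 +/- anisotropyJitter`. The mask is the set of voxel
#' centres inside the resulting ellipsoid. Seeds near the midline produce
#' midline-crossing lesions naturally. The returned ground truth records
#' each patient's total lesion volume and critical-region load (the lesioned
#' fraction of the critical region).
#'
#' @param config a [SimulationConfig-class].
#' @return A list with elements `lesions` (a [LesionVolumeSet-class]) and
#'   `truth` (data.frame: patient_id, volume_cm3, load).
#' @examples
#' cohort <- simulateLesionCohort(simulationConfig(nPatients = 3, seed = 7))
#' sapply(cohort$lesions@masks, sum)
#' @export
simulateLesionCohort <- function(config) {
  validObject(config)
  g <- config@gridShape
  vs <- config@voxelSizeMm
  affine <- centeredAffine(g, vs)
  n <- config@nPatients
  critLin <- voxLinear(config@criticalRegion, g)
  voxVol <- prod(vs) / 1000

  masks <- vector("list", n)
  loads <- numeric(n)
  withSeed(subSeed(config@seed, 1L), {
    for (p in seq_len(n)) {
      t <- sample.int(nrow(config@territorySeeds), 1L,
                      prob = config@territoryWeights)
      centre <- config@territorySeeds[t, ] + stats::rnorm(3L, 0, 2)
      centre <- round(pmin(pmax(centre, 1), g))  # snap to a voxel centre
      r <- stats::runif(1L, config@lesionRadiusRangeMm[1L],
                        config@lesionRadiusRangeMm[2L])
      a <- 1 + stats::runif(3L, -config@anisotropyJitter,
                            config@anisotropyJitter)
      d2 <- distanceField2(centre, a, g, vs)
      masks[[p]] <- array(as.numeric(d2 <= r^2), dim = g)
      loads[p] <- sum(masks[[p]][critLin]) / length(critLin)
    }
  })
  vols <- vapply(masks, function(m) sum(m) * voxVol, 0)
  ids <- sprintf("P%03d", seq_len(n))
  lesions <- new("LesionVolumeSet",
    patientIds = ids, masks = masks, affine = affine,
    voxelSizeMm = vs, volumesCm3 = vols
  )
  truth <- data.frame(patient_id = ids, volume_cm3 = vols, load = loads,
                      stringsAsFactors = FALSE)
  list(lesions = lesions, truth = truth)
}

#' Simulate continuous severity scores from lesion ground truth
#'
#' Linear lesion-deficit model:
#' `score_i = effectBeta * load_i + volumeGamma * volume_i + eps_i`,
#' with `eps_i ~ Normal(0, noiseSd^2)`, seeded from the config.
#'
#' @param loads per-patient critical-region load (fraction in [0, 1]).
#' @param volumesCm3 per-patient total lesion volume in cm^3.
#' @param config a [SimulationConfig-class] (supplies the coefficients,
#'   noise sd and seed).
#' @return Numeric vector of severity scores.
#' @export
simulateBehaviour <- function(loads, volumesCm3, config) {
  validObject(config)
  if (length(loads) != length(volumesCm3))
    stop("loads and volumesCm3 must have the same length", call. = FALSE)
  n <- length(loads)
  eps <- if (config@noiseSd > 0) {
    withSeed(subSeed(config@seed, 2L), stats::rnorm(n, 0, config@noiseSd))
  } else rep(0, n)
  config@effectBeta * loads + config@volumeGamma * volumesCm3 + eps
}

# Hearts-task page geometry (landscape A4, mm) and layout constants.
PAGE_X <- c(0, 297)
PAGE_Y <- c(0, 210)
PAGE_MARGIN <- 8
MIN_STIM_DIST <- 10
N_PER_TYPE <- 50L
EGO_SLOPE <- 20       # steepness of the logistic omission profile in u
ALLO_FP_MAX <- 0.8    # false-positive probability at severity 1

#' Simulate a Hearts cancellation sheet
#'
#' Places 150 heart stimuli (50 complete targets, 50 left-gap and 50
#' right-gap distractors) pseudorandomly on a landscape A4 page with a
#' minimum inter-stimulus distance, then marks them according to a
#' lateralised phenotype:
#'
#' * `none` - every complete target marked, no false positives.
#' * `left_ego` / `right_ego` - the probability of marking a complete
#'   target decays logistically toward the neglected side; at severity 1
#'   roughly half the page is omitted.
#' * `left_allo` / `right_allo` - all targets marked, plus gap-side-specific
#'   false positives on distractors with probability
#'   `severity * 0.8` (left-gap distractors for `left_allo`).
#'
#' @param phenotype one of `"none"`, `"left_ego"`, `"right_ego"`,
#'   `"left_allo"`, `"right_allo"`.
#' @param severity real in [0, 1].
#' @param seed RNG seed; layout and marking are reproducible.
#' @return A [CancellationSheet-class].
#' @examples
#' sh <- simulateSheet("left_ego", severity = 0.8, seed = 42)
#' scoreSheet(sh)
#' @export
simulateSheet <- function(phenotype = c("none", "left_ego", "right_ego",
                                        "left_allo", "right_allo"),
                          severity = 0, seed = 1L) {
  phenotype <- match.arg(phenotype)
  if (!is.numeric(severity) || severity < 0 || severity > 1)
    stop("severity must lie in [0, 1]", call. = FALSE)

  withSeed(seed, {
    xy <- placeStimuli(3L * N_PER_TYPE)
    # balance each stimulus type across the page halves (25 left, 25
    # right), as on the printed sheet: a full marking then has zero
    # expected asymmetry and no spurious impairment labels
    left <- xy[, 1L] < mean(PAGE_X)
    type <- character(nrow(xy))
    half <- rep(c("complete", "left_gap", "right_gap"), each = N_PER_TYPE / 2L)
    type[left] <- sample(half)
    type[!left] <- sample(half)
    u <- (xy[, 1L] - mean(PAGE_X)) / (diff(PAGE_X) / 2)
    marked <- markStimuli(phenotype, severity, type, u)
  })

  new("CancellationSheet",
    stimuli = data.frame(x = xy[, 1L], y = xy[, 2L], type = type,
                         marked = marked, stringsAsFactors = FALSE),
    pageXMin = PAGE_X[1L], pageXMax = PAGE_X[2L],
    pageYMin = PAGE_Y[1L], pageYMax = PAGE_Y[2L]
  )
}

# Dart-throwing placement with a minimum inter-stimulus distance; exactly
# half the stimuli fall in each page half (the printed sheet is laterally
# balanced).
placeStimuli <- function(n) {
  centre <- mean(PAGE_X)
  xs <- numeric(n); ys <- numeric(n)
  k <- 0L; tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > 2e5L) stop("could not place stimuli", call. = FALSE)
    xr <- if (k < n / 2L) c(PAGE_X[1L] + PAGE_MARGIN, centre - 1)
          else c(centre + 1, PAGE_X[2L] - PAGE_MARGIN)
    x <- stats::runif(1L, xr[1L], xr[2L])
    y <- stats::runif(1L, PAGE_Y[1L] + PAGE_MARGIN, PAGE_Y[2L] - PAGE_MARGIN)
    if (k == 0L ||
        min((xs[1:k] - x)^2 + (ys[1:k] - y)^2) >= MIN_STIM_DIST^2) {
      k <- k + 1L
      xs[k] <- x; ys[k] <- y
    }
  }
  cbind(xs, ys)
}

# Phenotype-specific marking probabilities. u is the signed page position
# in [-1, 1] (negative = left). For ego phenotypes the omission boundary
# sits at u = severity - 1 (neglected side), so severity 1 omits the left
# (resp. right) half of the page almost surely.
markStimuli <- function(phenotype, severity, type, u) {
  isTarget <- type == "complete"
  p <- numeric(length(u))
  p[isTarget] <- 1
  if (severity > 0) {
    if (phenotype == "left_ego") {
      cut <- severity - 1
      p[isTarget] <- 1 - severity *
        stats::plogis(EGO_SLOPE * (cut - u[isTarget]))
    } else if (phenotype == "right_ego") {
      cut <- severity - 1
      p[isTarget] <- 1 - severity *
        stats::plogis(EGO_SLOPE * (cut + u[isTarget]))
    } else if (phenotype == "left_allo") {
      p[type == "left_gap"] <- ALLO_FP_MAX * severity
    } else if (phenotype == "right_allo") {
      p[type == "right_gap"] <- ALLO_FP_MAX * severity
    }
  }
  stats::runif(length(u)) < p
}

#' Mirror a sheet about the page centre
#'
#' Reflects every stimulus about the vertical page midline
#' (`x -> xMin + xMax - x`) and swaps `left_gap` with `right_gap`
#' distractor types, preserving marks. Scoring a mirrored sheet negates all
#' lateralised scores and swaps left/right impairment labels.
#'
#' @param sheet a [CancellationSheet-class].
#' @return The mirrored [CancellationSheet-class].
#' @export
mirrorSheet <- function(sheet) {
  st <- sheet@stimuli
  st$x <- sheet@pageXMin + sheet@pageXMax - st$x
  st$type <- c(complete = "complete", left_gap = "right_gap",
               right_gap = "left_gap")[st$type]
  st$type <- unname(st$type)
  initialize(sheet, stimuli = st)
}
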