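# Shared fixtures: hand-built sheets, small cohort configs, toy maps.

# A sheet from explicit stimulus vectors (defaults: full A4 page).
makeSheet <- function(x, type, marked, y = rep(100, length(x)),
                      xRange = c(0, 297), yRange = c(0, 210)) {
  new("CancellationSheet",
    stimuli = data.frame(x = x, y = y, type = type, marked = marked,
                         stringsAsFactors = FALSE),
    pageXMin = xRange[1], pageXMax = xRange[2],
    pageYMin = yRange[1], pageYMax = yRange[2]
  )
}

# Small two-territory cohort on a 20x20x10 grid of 2 mm voxels. The
# critical region is a 6 mm sphere on the right-hemisphere territory seed.
smallGrid <- c(20L, 20L, 10L)
smallVox <- c(2, 2, 2)
critCentre <- c(14, 10, 5)

smallCohortConfig <- function(seed, nPatients = 40L, effectBeta = 0,
                              volumeGamma = 0, noiseSd = 1,
                              anisotropyJitter = 0.1) {
  simulationConfig(
    gridShape = smallGrid, voxelSizeMm = smallVox, nPatients = nPatients,
    criticalRegion = sphereRegion(critCentre, 6, smallGrid, smallVox),
    territorySeeds = rbind(critCentre, c(6, 10, 5)),
    lesionRadiusRangeMm = c(4, 12),
    effectBeta = effectBeta, volumeGamma = volumeGamma, noiseSd = noiseSd,
    anisotropyJitter = anisotropyJitter, seed = seed
  )
}

# The strong-effect recovery cohort: n = 60, beta = 2, noise sd = 0.02.
recoveryConfig <- function(seed) {
  smallCohortConfig(seed, nPatients = 60L, effectBeta = 2,
                    volumeGamma = 0.005, noiseSd = 0.02)
}

# Binary array for the implanted critical region of a config.
criticalArray <- function(config) {
  arr <- array(0, dim = config@gridShape)
  arr[config@criticalRegion] <- 1
  arr
}

diceCoef <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))

# A ThresholdedMap from explicit significant voxel indices (n x 3).
makeThrMap <- function(vox, gridShape = smallGrid, voxelSizeMm = smallVox,
                       zCut = 5) {
  arr <- array(0, dim = gridShape)
  if (length(vox)) arr[matrix(as.integer(vox), ncol = 3L)] <- 1
  new("ThresholdedMap",
    significant = arr, zCut = zCut, alphaCorrected = 0.05,
    nSignificant = as.integer(sum(arr)),
    affine = neglectVLSM:::centeredAffine(gridShape, voxelSizeMm),
    provenance = list()
  )
}

# TRUE when every nonzero voxel of a 3-D array is reachable from the first
# one through face-adjacent (6-connected) nonzero neighbours.
isConnected6 <- function(arr) {
  d <- dim(arr)
  on <- which(arr != 0)
  if (length(on) <= 1L) return(length(on) == 1L)
  idx <- array(0L, dim = d)
  idx[on] <- seq_along(on)
  vox <- which(arr != 0, arr.ind = TRUE)
  seen <- logical(length(on))
  queue <- 1L
  seen[1L] <- TRUE
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    cur <- vox[queue[1L], ]
    queue <- queue[-1L]
    for (s in 1:6) {
      nb <- cur + steps[s, ]
      if (any(nb < 1L) || any(nb > d)) next
      j <- idx[nb[1L], nb[2L], nb[3L]]
      if (j > 0L && !seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(seen)
}
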