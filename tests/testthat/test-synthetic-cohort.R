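# Synthetic cohort generator: determinism, blob geometry, behavioural
# model, sheet counts and phenotype monotonicity.

test_that("cohort simulation is deterministic and handles n = 0", {
  cfg <- smallCohortConfig(seed = 21, nPatients = 6L)
  a <- simulateLesionCohort(cfg)
  b <- simulateLesionCohort(cfg)
  expect_identical(a$lesions@masks, b$lesions@masks)
  expect_identical(a$truth, b$truth)

  empty <- simulateLesionCohort(smallCohortConfig(seed = 1, nPatients = 0L))
  expect_length(empty$lesions@masks, 0)
  expect_identical(nrow(empty$truth), 0L)
})

test_that("masks are binary, nonempty and 6-connected", {
  cohort <- simulateLesionCohort(smallCohortConfig(seed = 33, nPatients = 12L))
  for (m in cohort$lesions@masks) {
    expect_true(all(m %in% c(0, 1)))
    expect_gt(sum(m), 0)
    expect_true(isConnected6(m))
  }
})

test_that("fixed-radius spherical blobs match a brute-force distance count", {
  g <- c(30L, 30L, 20L)
  vs <- c(2, 2, 2)
  r <- 9
  cfg <- simulationConfig(
    gridShape = g, voxelSizeMm = vs, nPatients = 5L,
    criticalRegion = matrix(c(15L, 15L, 10L), 1L),
    territorySeeds = matrix(c(15, 15, 10), 1L),
    lesionRadiusRangeMm = c(r, r), anisotropyJitter = 0,
    noiseSd = 0, seed = 4
  )
  cohort <- simulateLesionCohort(cfg)
  voxVol <- prod(vs) / 1000
  for (m in cohort$lesions@masks) {
    # centroid of a symmetric sphere = mean voxel centre of the mask
    vox <- which(m != 0, arr.ind = TRUE)
    centre <- colMeans(vox)
    # brute-force enumeration of voxel centres within r mm of the centroid
    d2 <- outer(outer(((seq_len(g[1]) - centre[1]) * vs[1])^2,
                      ((seq_len(g[2]) - centre[2]) * vs[2])^2, "+"),
                ((seq_len(g[3]) - centre[3]) * vs[3])^2, "+")
    expect_equal(sum(m) * voxVol, sum(d2 <= r^2) * voxVol)
  }
})

test_that("ground-truth loads are the lesioned fraction of the region", {
  cfg <- smallCohortConfig(seed = 8, nPatients = 10L)
  cohort <- simulateLesionCohort(cfg)
  crit <- criticalArray(cfg)
  manual <- vapply(cohort$lesions@masks,
                   function(m) sum(m * crit) / sum(crit), 0)
  expect_equal(cohort$truth$load, manual)
  expect_true(all(cohort$truth$load >= 0 & cohort$truth$load <= 1))
})

test_that("behaviour follows the linear lesion-deficit model", {
  cfg <- smallCohortConfig(seed = 2, effectBeta = 0, volumeGamma = 0,
                           noiseSd = 0)
  expect_equal(simulateBehaviour(c(0.1, 0.9), c(1, 2), cfg), c(0, 0))

  cfg2 <- smallCohortConfig(seed = 2, effectBeta = 1, volumeGamma = 0,
                            noiseSd = 0)
  expect_equal(simulateBehaviour(c(0.2, 0.8), c(5, 5), cfg2), c(0.2, 0.8))

  cfg3 <- smallCohortConfig(seed = 2, effectBeta = 2, volumeGamma = 0.5,
                            noiseSd = 0)
  expect_equal(simulateBehaviour(c(0.5, 0), c(2, 4), cfg3), c(2, 2))

  expect_error(simulateBehaviour(c(1, 2), c(1, 2, 3), cfg), "length")

  # law-of-large-numbers bound on the noise mean at beta = 0
  cfg4 <- smallCohortConfig(seed = 99, effectBeta = 0, volumeGamma = 0,
                            noiseSd = 0.1)
  sc <- simulateBehaviour(rep(0, 1000), rep(0, 1000), cfg4)
  expect_lt(abs(mean(sc)), 4 * 0.1 / sqrt(1000))
})

test_that("sheets carry 50 stimuli of each type for every phenotype", {
  for (ph in c("none", "left_ego", "right_ego", "left_allo", "right_allo")) {
    sh <- simulateSheet(ph, 0.6, seed = 77)
    counts <- table(sh@stimuli$type)
    expect_identical(as.integer(counts[c("complete", "left_gap",
                                         "right_gap")]),
                     c(50L, 50L, 50L))
    expect_true(validateStandardSheet(sh))
  }
  expect_error(simulateSheet("sideways", 0.5, seed = 1))
  expect_error(simulateSheet("left_ego", 1.5, seed = 1), "severity")
})

test_that("sheet simulation is deterministic and respects spacing", {
  a <- simulateSheet("left_ego", 0.5, seed = 123)
  b <- simulateSheet("left_ego", 0.5, seed = 123)
  expect_identical(a@stimuli, b@stimuli)
  d <- as.matrix(dist(a@stimuli[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 10)
})

test_that("severity 1 left neglect spares no leftmost-third targets", {
  sh <- simulateSheet("left_ego", 1, seed = 42)
  st <- sh@stimuli
  leftThird <- st$x < sh@pageXMin + (sh@pageXMax - sh@pageXMin) / 3
  expect_false(any(st$marked[leftThird & st$type == "complete"]))
  expect_gt(centerOfCancellation(sh), 0)
})

test_that("scored severities increase with the severity parameter", {
  sevs <- c(0, 0.25, 0.5, 0.75, 1)
  meanScore <- function(ph, extract) {
    vapply(seq_along(sevs), function(i) {
      mean(vapply(1:100, function(j) {
        extract(scoreSheet(simulateSheet(ph, sevs[i],
                                         seed = 1000 * i + j)))
      }, 0))
    }, 0)
  }
  ego <- meanScore("left_ego", egoCoc)
  expect_true(all(diff(ego) > -0.02))
  expect_gt(ego[5], ego[1] + 0.2)
  allo <- meanScore("left_allo", alloScore)
  expect_true(all(diff(allo) > -0.02))
  expect_gt(allo[5], allo[1] + 0.1)
})
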