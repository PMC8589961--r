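# Mass-univariate core: overlap filter, residualization, pooled t,
# Bonferroni threshold, and the assembled pipeline invariants.

test_that("overlap filter is inclusive at the minimum", {
  design <- cbind(c(rep(1, 9), rep(0, 11)),   # 9 lesioned
                  c(rep(1, 10), rep(0, 10)),  # 10 lesioned
                  rep(0, 20))                 # 0 lesioned
  inc <- overlapFilter(design, 10)
  expect_identical(inc, 2L)
  expect_length(overlapFilter(matrix(0, 5, 4), 10), 0)
})

test_that("residualization matches the closed-form simple regression", {
  v <- c(1, 2, 3, 4, 5)
  expect_equal(as.numeric(residualizeScores(2 * v, v)), rep(0, 5))

  # orthogonal scores: residuals are just the centred scores
  s <- c(1, -1, 0, 1, -1); s <- s - mean(s)
  vC <- v - mean(v)
  sOrth <- s - sum(s * vC) / sum(vC^2) * vC
  expect_equal(as.numeric(residualizeScores(sOrth, v)),
               sOrth - mean(sOrth), tolerance = 1e-12)

  # closed form a + b*v with b = cov(s, v) / var(v), n = 50
  set.seed(7)
  s <- rnorm(50); v50 <- rnorm(50, 10, 3)
  b <- cov(s, v50) / var(v50)
  a <- mean(s) - b * mean(v50)
  res <- residualizeScores(s, v50)
  expect_equal(as.numeric(res), s - (a + b * v50), tolerance = 1e-10)
  expect_lt(abs(sum(res)), 1e-10)
  expect_lt(abs(sum(res * v50)), 1e-8)

  expect_warning(rc <- residualizeScores(s[1:5], rep(2, 5)), "constant")
  expect_true(attr(rc, "degenerate"))
  expect_equal(as.numeric(rc), s[1:5] - mean(s[1:5]))
  expect_error(residualizeScores(1:2, 1:2), "at least 3")
})

test_that("the pooled t matches the hand-evaluated closed form", {
  scores <- c(2, 3, 0, 1)
  design <- matrix(c(1, 1, 0, 0), ncol = 1)
  out <- voxelTTest(design, scores, "positive")
  # m1 = 2.5, m2 = 0.5, sp2 = 0.5, se = sqrt(0.5 * (1/2 + 1/2))
  expect_equal(out$t, 2 / sqrt(0.5), tolerance = 1e-12)
  expect_identical(out$df, 2L)
  # cross-check against the reference pooled t routine
  ref <- t.test(scores[design[, 1] == 1], scores[design[, 1] == 0],
                var.equal = TRUE)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-12)

  # identical group means -> t = 0, one-tailed p = 0.5, z = 0
  out0 <- voxelTTest(matrix(c(1, 1, 0, 0), ncol = 1), c(1, 2, 1, 2),
                     "positive")
  expect_equal(out0$t, 0)
  expect_equal(out0$z, 0)

  # permuting subjects leaves (t, z) unchanged
  perm <- c(3, 1, 4, 2)
  outP <- voxelTTest(design[perm, , drop = FALSE], scores[perm], "positive")
  expect_equal(outP$t, out$t)
  expect_equal(outP$z, out$z)

  # direction = "negative" flips the orientation
  outN <- voxelTTest(design, scores, "negative")
  expect_equal(outN$t, -out$t)

  # groups of < 2 members are untestable
  outU <- voxelTTest(matrix(c(1, 0, 0, 0), ncol = 1), scores, "positive")
  expect_true(is.na(outU$t))
})

test_that("z conversion goes through the exact t tail", {
  design <- matrix(rep(c(1, 0), each = 10), ncol = 1)
  set.seed(3)
  s <- rnorm(20) + design[, 1]
  out <- voxelTTest(design, s, "positive")
  expect_equal(out$z,
               qnorm(pt(out$t, 18, lower.tail = FALSE), lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("Bonferroni threshold arithmetic and monotonicity", {
  b1 <- bonferroniThreshold(0.05, 1)
  expect_equal(b1$alphaCorrected, 0.05)
  expect_equal(b1$zCut, qnorm(0.95), tolerance = 1e-12)

  b20 <- bonferroniThreshold(0.05, 20)
  expect_equal(b20$alphaCorrected, 0.0025)
  expect_equal(b20$zCut, qnorm(0.9975), tolerance = 1e-12)

  # z_cut nondecreasing in n_tests
  zc <- vapply(c(1, 10, 100, 1e4, 1e6), function(n)
    bonferroniThreshold(0.05, n)$zCut, 0)
  expect_true(all(diff(zc) > 0))
  expect_error(bonferroniThreshold(0.05, 0), "at least 1")
  expect_error(bonferroniThreshold(1.2, 10), "alphaFamily")
})

test_that("runVlsm assembles the stages and records a manifest", {
  cfg <- recoveryConfig(seed = 5)
  cohort <- simulateLesionCohort(cfg)
  sev <- simulateBehaviour(cohort$truth$load, cohort$truth$volume_cm3, cfg)
  cm <- cohortMatrix(cohort$lesions, sev)
  res <- runVlsm(cm, minOverlap = 10)

  expect_identical(res$manifest$n_tests, nTests(res$stat))
  expect_identical(res$manifest$df, 58L)
  expect_equal(res$manifest$alpha_corrected, 0.05 / res$manifest$n_tests)
  expect_identical(res$manifest$n_significant,
                   nSignificant(res$thresholded))
  # every significant voxel was included
  sigLin <- which(significantArray(res$thresholded) != 0)
  incLin <- neglectVLSM:::voxLinear(includedVoxels(res$stat), cfg@gridShape)
  expect_true(all(sigLin %in% incLin))
  # all z at significant voxels exceed the cut
  expect_true(all(zValues(res$stat)[match(sigLin, incLin)] >=
                  zCut(res$thresholded)))

  # constant scores -> nothing significant
  resC <- runVlsm(cohortMatrix(cohort$lesions, rep(1, 60)), minOverlap = 10)
  expect_identical(resC$manifest$n_significant, 0L)

  # zero included voxels -> empty maps, n_tests = 0, no exception
  resE <- runVlsm(cm, minOverlap = 1000L)
  expect_identical(resE$manifest$n_tests, 0L)
  expect_identical(nSignificant(resE$thresholded), 0L)
})

test_that("n_significant is nonincreasing in the z cut", {
  cfg <- recoveryConfig(seed = 9)
  cohort <- simulateLesionCohort(cfg)
  sev <- simulateBehaviour(cohort$truth$load, cohort$truth$volume_cm3, cfg)
  cm <- cohortMatrix(cohort$lesions, sev)
  ns <- vapply(c(0.2, 0.05, 0.01, 0.001), function(a)
    runVlsm(cm, alphaFamily = a, minOverlap = 10)$manifest$n_significant, 0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("an empty-lesion subject at the mean score does not change inclusion", {
  cfg <- smallCohortConfig(seed = 14, nPatients = 20L)
  cohort <- simulateLesionCohort(cfg)
  sev <- simulateBehaviour(cohort$truth$load, cohort$truth$volume_cm3, cfg)
  inc <- overlapFilter(cohortMatrix(cohort$lesions, sev)@design, 5)

  les2 <- cohort$lesions
  les2@masks <- c(les2@masks, list(array(0, dim = smallGrid)))
  les2@patientIds <- c(les2@patientIds, "P_EMPTY")
  les2@volumesCm3 <- c(les2@volumesCm3, 0)
  inc2 <- overlapFilter(cohortMatrix(les2, c(sev, mean(sev)))@design, 5)
  expect_identical(inc, inc2)
})

test_that("adding c * volume to all scores leaves the t map unchanged", {
  cfg <- smallCohortConfig(seed = 6, nPatients = 30L, effectBeta = 1,
                           noiseSd = 0.3)
  cohort <- simulateLesionCohort(cfg)
  sev <- simulateBehaviour(cohort$truth$load, cohort$truth$volume_cm3, cfg)
  cm1 <- cohortMatrix(cohort$lesions, sev)
  cm2 <- cohortMatrix(cohort$lesions, sev + 3.7 * cohort$lesions@volumesCm3)
  t1 <- runVlsm(cm1, minOverlap = 5)$stat
  t2 <- runVlsm(cm2, minOverlap = 5)$stat
  expect_equal(tValues(t1), tValues(t2), tolerance = 1e-8)
})
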