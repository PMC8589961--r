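# Map post-processing: overlap, mirror homologue, atlas coverage, peak
# lookup and lesion overlays.

test_that("map overlap counts and percentages are exact", {
  a <- makeThrMap(cbind(1:4, 1, 1))
  expect_s4_class(mapOverlap(a, a), "OverlapReport")
  expect_equal(mapOverlap(a, a)@pctOfA, 100)
  expect_equal(mapOverlap(a, a)@pctOfB, 100)

  b <- makeThrMap(cbind(10:13, 5, 5))
  expect_identical(mapOverlap(a, b)@nCommon, 0L)

  # |A| = 200, |B| = 100, |A n B| = 50 -> 25% of A, 50% of B
  allV <- which(array(TRUE, smallGrid), arr.ind = TRUE)
  A <- makeThrMap(allV[1:200, ])
  B <- makeThrMap(allV[151:250, ])
  ov <- mapOverlap(A, B)
  expect_identical(ov@nCommon, 50L)
  expect_equal(ov@pctOfA, 25)
  expect_equal(ov@pctOfB, 50)

  # empty map flagged undefined
  e <- makeThrMap(matrix(numeric(), 0, 3))
  ovE <- mapOverlap(e, a)
  expect_true(ovE@undefinedA)
  expect_equal(ovE@pctOfA, 0)

  small <- makeThrMap(cbind(1, 1, 1), gridShape = c(4L, 4L, 4L))
  expect_error(mapOverlap(a, small), "grid")
})

test_that("mirroring reflects through world x = 0 and is an involution", {
  # even-dimension centred grid: voxel centres symmetric about x = 0
  m <- makeThrMap(rbind(c(16, 10, 5), c(18, 3, 2)))
  mm <- mirrorHomologue(m)
  expect_identical(nSignificant(mm), nSignificant(m))
  # world x = +10 mm maps to -10 mm
  wx <- worldXMap(smallGrid, m@affine)
  origX <- wx[16, 10, 5]
  mirVox <- which(significantArray(mm) != 0, arr.ind = TRUE)
  expect_true(any(abs(wx[mirVox] + origX) < 1e-9))
  # involution
  back <- mirrorHomologue(mm)
  expect_identical(significantArray(back), significantArray(m))

  # a midline-symmetric map is unchanged
  sym <- makeThrMap(rbind(c(5, 7, 3), c(16, 7, 3)))  # 5 and 16 mirror (dim 20)
  expect_identical(significantArray(mirrorHomologue(sym)),
                   significantArray(sym))
})

test_that("asymmetric grids warn and out-of-field reflections are dropped", {
  # shift the affine so the grid is not symmetric about x = 0
  m <- makeThrMap(cbind(19, 10, 5))
  m@affine[1, 4] <- m@affine[1, 4] + 0.5
  expect_warning(mm <- mirrorHomologue(m), "symmetric")

  # a voxel whose reflection falls outside the field of view is dropped
  m2 <- makeThrMap(cbind(20, 10, 5), gridShape = c(20L, 20L, 10L))
  m2@affine[1, 4] <- m2@affine[1, 4] + 4  # world x range now asymmetric
  suppressWarnings(mm2 <- mirrorHomologue(m2))
  expect_identical(nSignificant(mm2), 0L)
  expect_identical(mm2@provenance$mirror_dropped, 1L)
})

test_that("atlas fractions report per-ROI coverage sorted by n_sig", {
  lab <- array(0L, dim = smallGrid)
  lab[1:5, 1:10, 1:10] <- 1L        # ROI 1: 500 voxels
  lab[10:19, 1:20, 1:10] <- 2L      # ROI 2: 2000 voxels
  names <- data.frame(label = c(1L, 2L, 3L),
                      name = c("roiA", "roiB", "roiEmpty"),
                      atlas = c("TOY", "TOY", "TOY"))
  atlas <- new("AtlasLabels", labelVolume = lab, names = names)

  # full coverage of ROI 1 plus 220 voxels of ROI 2
  roi1 <- which(lab == 1L, arr.ind = TRUE)
  roi2 <- which(lab == 2L, arr.ind = TRUE)
  map <- makeThrMap(rbind(roi1, roi2[1:220, ]))
  expect_warning(rep <- atlasFractions(map, atlas), "roiEmpty")
  expect_identical(rep$name, c("roiA", "roiB"))  # sorted by n_sig desc
  expect_identical(rep$n_sig, c(500L, 220L))
  expect_equal(rep$fraction, c(100, 11))
  expect_identical(attr(rep, "n_outside"), 0L)

  # disjoint ROI omitted; off-atlas voxels counted
  off <- makeThrMap(cbind(7:8, 15, 5))   # background voxels
  suppressWarnings(repOff <- atlasFractions(off, atlas))
  expect_identical(nrow(repOff), 0L)
  expect_identical(attr(repOff, "n_outside"), 2L)

  # coverage never exceeds the significant count
  expect_lte(sum(rep$n_sig), nSignificant(map))
})

test_that("peak voxel returns the maximum z with lexicographic ties", {
  aff <- neglectVLSM:::centeredAffine(smallGrid, smallVox)
  vox <- rbind(c(3, 3, 3), c(2, 5, 5), c(10, 1, 1))
  stat <- new("StatMap",
    tValues = c(4, 6, 6), zValues = c(3.5, 5.5, 5.5), df = 38L,
    voxels = matrix(as.integer(vox), ncol = 3), nTests = 3L,
    minOverlap = 10L, nUntestable = 0L, gridShape = smallGrid,
    affine = aff)
  pk <- peakVoxel(stat)
  expect_equal(pk$z, 5.5)
  expect_identical(pk$voxel, c(2L, 5L, 5L))   # smallest voxel index wins
  expect_true(pk$tied)
  expect_equal(pk$world,
               as.numeric(neglectVLSM:::voxelToWorldMat(c(2, 5, 5), aff)))

  empty <- new("StatMap", tValues = numeric(), zValues = numeric(),
               df = 0L, voxels = matrix(integer(), 0, 3), nTests = 0L,
               minOverlap = 10L, nUntestable = 0L, gridShape = smallGrid,
               affine = aff)
  expect_error(peakVoxel(empty), "empty")
})

test_that("the peak of a recovered effect sits at the implanted centroid", {
  cfg <- recoveryConfig(seed = 3)
  cohort <- simulateLesionCohort(cfg)
  sev <- simulateBehaviour(cohort$truth$load, cohort$truth$volume_cm3, cfg)
  res <- runVlsm(cohortMatrix(cohort$lesions, sev), minOverlap = 10)
  pk <- peakVoxel(res$stat)
  expect_lte(max(abs(pk$voxel - critCentre)), 1)
})

test_that("overlay counts sum masks voxelwise", {
  m <- array(0, c(6, 6, 4)); m[2:3, 2:3, 2] <- 1
  les <- new("LesionVolumeSet", patientIds = c("a", "b", "c"),
             masks = list(m, m, m),
             affine = neglectVLSM:::centeredAffine(c(6L, 6L, 4L), c(1, 1, 1)),
             voxelSizeMm = c(1, 1, 1),
             volumesCm3 = rep(sum(m) / 1000, 3))
  expect_equal(overlayCount(les), 3 * m)

  m2 <- array(0, c(6, 6, 4)); m2[5, 5, 3] <- 1
  les@masks <- list(m, m2); les@patientIds <- c("a", "b")
  les@volumesCm3 <- c(sum(m), sum(m2)) / 1000
  ov <- overlayCount(les)
  expect_true(all(ov %in% c(0, 1)))          # disjoint masks

  mShared <- array(0, c(6, 6, 4)); mShared[2:3, 2, 2] <- 1
  les@masks <- list(m, mShared)
  les@volumesCm3 <- c(sum(m), sum(mShared)) / 1000
  expect_identical(sum(overlayCount(les) == 2), 2L)  # k shared voxels
  expect_lte(max(overlayCount(les)), 2)
})
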