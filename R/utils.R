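# Internal helpers: scoped RNG and voxel/world geometry.

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards so simulation calls never perturb the
# user's RNG stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream label.
subSeed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + stream * 7919L
}

# Grid-centred affine: diagonal voxel sizes, voxel centres symmetric about
# world 0 on every axis (so the midsagittal plane x = 0 bisects the grid).
centeredAffine <- function(gridShape, voxelSizeMm) {
  aff <- diag(c(voxelSizeMm, 1))
  aff[1:3, 4L] <- -voxelSizeMm * (gridShape - 1) / 2
  aff
}

# 1-based voxel indices (n x 3) -> world mm (n x 3). NIfTI affines map
# 0-based indices, hence the -1.
voxelToWorldMat <- function(vox, affine) {
  vox <- matrix(as.numeric(vox), ncol = 3L)
  h <- cbind(vox - 1, 1)
  w <- h %*% t(affine)
  w[, 1:3, drop = FALSE]
}

# World mm (n x 3) -> continuous 1-based voxel coordinates (n x 3).
worldToVoxelMat <- function(world, affine) {
  world <- matrix(as.numeric(world), ncol = 3L)
  h <- cbind(world, 1)
  v <- h %*% t(solve(affine))
  v[, 1:3, drop = FALSE] + 1
}

# Voxel-centre world coordinates of every grid voxel, as three vectors.
gridWorldAxes <- function(gridShape, affine) {
  stopifnot(all(abs(affine[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))]) < 1e-9))
  lapply(1:3, function(a) affine[a, a] * (seq_len(gridShape[a]) - 1) + affine[a, 4L])
}

# n x 3 1-based voxel index matrix -> linear indices into an array.
voxLinear <- function(vox, gridShape) {
  (vox[, 3L] - 1L) * gridShape[1L] * gridShape[2L] +
    (vox[, 2L] - 1L) * gridShape[1L] + vox[, 1L]
}

# Linear indices -> n x 3 1-based voxel index matrix.
linearVox <- function(lin, gridShape) {
  lin0 <- lin - 1L
  i <- lin0 %% gridShape[1L]
  j <- (lin0 %/% gridShape[1L]) %% gridShape[2L]
  k <- lin0 %/% (gridShape[1L] * gridShape[2L])
  cbind(i, j, k) + 1L
}

# Stable content hash of an R object (used for run manifests).
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
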