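# Stage orchestration: simulate -> score -> vlsm -> compare -> describe,
# with a YAML config, delimited-text tables, NIfTI volumes and JSON run
# manifests. Each stage logs its headline counts so pipeline numbers
# (patients read, voxels included, voxels significant) are traceable.

#' Read a simulation config from YAML
#'
#' Recognised keys mirror [simulationConfig()] arguments in snake_case
#' (`grid_shape`, `voxel_size_mm`, `n_patients`, `lesion_radius_range_mm`,
#' `effect_beta`, `volume_gamma`, `noise_sd`, `anisotropy_jitter`, `seed`,
#' `territory_seeds`, `territory_weights`). `critical_region` is given as
#' `{centre_vox: [i, j, k], radius_mm: r}`. An optional `sheets` block
#' (`phenotype`, `severity_scale`) controls sheet simulation.
#'
#' @param path YAML file path.
#' @return List with elements `config` (a [SimulationConfig-class]) and
#'   `sheets` (a list: phenotype, severity_scale).
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- as.integer(y$grid_shape %||% c(40L, 40L, 30L))
  vs <- as.numeric(y$voxel_size_mm %||% c(2, 2, 2))
  crit <- NULL
  if (!is.null(y$critical_region)) {
    cr <- y$critical_region
    crit <- sphereRegion(as.numeric(cr$centre_vox), as.numeric(cr$radius_mm),
                         grid, vs)
  }
  seeds <- if (!is.null(y$territory_seeds))
    do.call(rbind, lapply(y$territory_seeds, as.numeric)) else NULL
  cfg <- simulationConfig(
    gridShape = grid, voxelSizeMm = vs,
    nPatients = y$n_patients %||% 40L,
    criticalRegion = crit,
    territorySeeds = seeds,
    territoryWeights = if (!is.null(y$territory_weights))
      as.numeric(y$territory_weights) else NULL,
    lesionRadiusRangeMm = as.numeric(y$lesion_radius_range_mm %||% c(5, 20)),
    effectBeta = y$effect_beta %||% 1,
    volumeGamma = y$volume_gamma %||% 0.01,
    noiseSd = y$noise_sd %||% 0.1,
    anisotropyJitter = y$anisotropy_jitter %||% 0.1,
    seed = y$seed %||% 1L
  )
  sheets <- list(
    phenotype = (y$sheets$phenotype) %||% "left_ego",
    severity_scale = (y$sheets$severity_scale) %||% 1
  )
  list(config = cfg, sheets = sheets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate stage: cohort volumes, sheets and manifest
#'
#' Generates the lesion cohort and behaviour from a YAML config, writes one
#' NIfTI mask per patient plus `manifest.tsv` (patient_id, file,
#' sheet_file, volume_cm3, load, score, seed), writes one cancellation
#' sheet per patient under `sheets/` (sheet severity is the behavioural
#' score scaled by `sheets$severity_scale` and clamped to [0, 1]), and a
#' JSON run manifest with the config hash.
#'
#' @param configFile YAML config path.
#' @param outDir output directory.
#' @param quiet suppress stage logging.
#' @return The output directory, invisibly.
#' @export
pipelineSimulate <- function(configFile, outDir, quiet = FALSE) {
  cf <- readSimulationConfig(configFile)
  cfg <- cf$config
  cohort <- simulateLesionCohort(cfg)
  scores <- simulateBehaviour(cohort$truth$load, cohort$truth$volume_cm3, cfg)
  n <- cfg@nPatients

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sheetDir <- file.path(outDir, "sheets")
  dir.create(sheetDir, showWarnings = FALSE)
  sheetFiles <- character(n)
  sev <- pmin(pmax(scores * cf$sheets$severity_scale, 0), 1)
  for (i in seq_len(n)) {
    sh <- simulateSheet(cf$sheets$phenotype, sev[i],
                        seed = subSeed(cfg@seed, 100L + i))
    sheetFiles[i] <- file.path("sheets",
                               paste0(cohort$lesions@patientIds[i], ".tsv"))
    writeSheet(sh, file.path(outDir, sheetFiles[i]))
  }
  extra <- data.frame(sheet_file = sheetFiles, load = cohort$truth$load,
                      score = scores, seed = rep(cfg@seed, n),
                      stringsAsFactors = FALSE)
  writeMaskSet(cohort$lesions, outDir, extra = extra)

  manifest <- list(
    stage = "simulate", config_hash = configHash(yaml::read_yaml(configFile)),
    seed = cfg@seed, n_patients = n,
    grid_shape = cfg@gridShape, voxel_size_mm = cfg@voxelSizeMm,
    n_critical_voxels = nrow(cfg@criticalRegion)
  )
  writeRunManifest(manifest, file.path(outDir, "run_manifest.json"))
  if (!quiet)
    message(sprintf("simulate: wrote %d mask(s) and %d sheet(s) to %s",
                    n, n, outDir))
  invisible(outDir)
}

#' Score stage: batch-score a directory of sheets
#'
#' Scores every `*.tsv` sheet in a directory and writes a tab-separated
#' table with columns patient_id, total_hits, ego_coc, ego_asym,
#' allo_score, allo_asym, labels, excluded.
#'
#' @param sheetsDir directory of sheet files.
#' @param outFile output TSV path.
#' @param quiet suppress stage logging.
#' @return The scores data.frame, invisibly.
#' @export
pipelineScore <- function(sheetsDir, outFile, quiet = FALSE) {
  files <- sort(list.files(sheetsDir, pattern = "\\.tsv$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    scoresAsRow(scoreSheet(readSheet(f)), sub("\\.tsv$", "", basename(f)))
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), total_hits = integer(),
               ego_coc = numeric(), ego_asym = integer(),
               allo_score = numeric(), allo_asym = integer(),
               labels = character(), excluded = logical(),
               stringsAsFactors = FALSE)
  utils::write.table(tab, outFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!quiet)
    message(sprintf("score: %d sheet(s) scored, %d excluded",
                    nrow(tab), sum(tab$excluded)))
  invisible(tab)
}

#' VLSM stage: masks + scores -> statistic and thresholded volumes
#'
#' Reads the mask set named by a simulate-stage manifest, joins the scores
#' table by patient id (dropping excluded patients), runs the full
#' mass-univariate analysis and writes `zmap.nii.gz` (z at tested voxels,
#' 0 elsewhere), `sig.nii.gz` (binary significant map) and
#' `vlsm_manifest.json` recording n_tests, alpha_corrected, z_cut, df and
#' n_significant.
#'
#' @param masksDir directory holding the masks and `manifest.tsv`.
#' @param scoresFile scores TSV from [pipelineScore()].
#' @param outDir output directory.
#' @param measure scores column to analyse: `"ego_coc"` or `"allo_score"`.
#' @param direction one-tailed test direction (see [cohortMatrix()]).
#' @param minOverlap minimum lesioned-patient count per voxel.
#' @param alpha family-wise alpha.
#' @param quiet suppress stage logging.
#' @return The [runVlsm()] result list, invisibly.
#' @export
pipelineVlsm <- function(masksDir, scoresFile, outDir,
                         measure = c("ego_coc", "allo_score"),
                         direction = c("positive", "negative"),
                         minOverlap = 10L, alpha = 0.05, quiet = FALSE) {
  measure <- match.arg(measure)
  direction <- match.arg(direction)
  man <- utils::read.table(file.path(masksDir, "manifest.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  scores <- utils::read.table(scoresFile, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  merged <- merge(man, scores, by = "patient_id", sort = TRUE)
  merged <- merged[!merged$excluded & !is.na(merged[[measure]]), ,
                   drop = FALSE]
  if (nrow(merged) < 3L)
    stop("fewer than 3 scorable patients after exclusion", call. = FALSE)
  lesions <- readMaskSet(file.path(masksDir, merged$file),
                         patientIds = merged$patient_id)
  cohort <- cohortMatrix(lesions, merged[[measure]], direction)
  res <- runVlsm(cohort, alphaFamily = alpha, minOverlap = minOverlap)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeStatMapNifti(res$stat, file.path(outDir, "zmap.nii.gz"))
  writeThresholdedMap(res$thresholded, file.path(outDir, "sig.nii.gz"))
  manifest <- c(list(stage = "vlsm", measure = measure,
                     n_patients_in = nrow(man),
                     n_patients_used = nrow(merged)),
                res$manifest)
  writeRunManifest(manifest, file.path(outDir, "vlsm_manifest.json"))
  if (!quiet)
    message(sprintf(
      "vlsm: %d patient(s), %d voxel(s) tested, z_cut %.3f, %d significant",
      nrow(merged), res$manifest$n_tests,
      res$manifest$z_cut %||% NA_real_, res$manifest$n_significant))
  invisible(res)
}

#' Compare stage: overlap between two thresholded maps
#'
#' Loads two binary significance volumes and reports their overlap.
#' With `mirror = TRUE` map B is first reflected across the midsagittal
#' plane (world x = 0) and midline voxel centres (|x| below half a voxel
#' width) are excluded from both maps, so the comparison is between
#' hemisphere homologues.
#'
#' @param mapAFile,mapBFile NIfTI paths of binary significance maps.
#' @param mirror mirror map B before comparing.
#' @param outFile optional JSON output path.
#' @param quiet suppress stage logging.
#' @return An [OverlapReport-class], invisibly.
#' @export
pipelineCompare <- function(mapAFile, mapBFile, mirror = FALSE,
                            outFile = NULL, quiet = FALSE) {
  a <- readThresholdedMap(mapAFile)
  b <- readThresholdedMap(mapBFile)
  if (mirror) {
    b <- mirrorHomologue(b)
    a <- dropMidline(a)
    b <- dropMidline(b)
  }
  rep <- mapOverlap(a, b)
  if (!is.null(outFile))
    writeRunManifest(list(stage = "compare", mirror = mirror,
                          n_common = rep@nCommon, pct_of_A = rep@pctOfA,
                          pct_of_B = rep@pctOfB,
                          undefined_A = rep@undefinedA,
                          undefined_B = rep@undefinedB), outFile)
  if (!quiet)
    message(sprintf("compare: %d common voxel(s); %.2f%% of A, %.2f%% of B",
                    rep@nCommon, rep@pctOfA, rep@pctOfB))
  invisible(rep)
}

# Zero out voxels whose centres sit within half a voxel width of the
# midsagittal plane; homologue comparisons are between hemispheres proper.
dropMidline <- function(map) {
  g <- dim(map@significant)
  wx <- worldXMap(g, map@affine)
  halfVox <- abs(map@affine[1L, 1L]) / 2
  sig <- map@significant
  sig[abs(wx) < halfVox - 1e-9] <- 0
  initialize(map, significant = sig, nSignificant = as.integer(sum(sig)))
}

#' Describe stage: atlas-based cluster description
#'
#' Loads a binary significance map, an integer-label atlas volume and a
#' names table (TSV: label, name, atlas), and writes the per-ROI coverage
#' report (name, atlas, n_sig, fraction, sorted by n_sig descending) as
#' tab-separated text. Voxels outside every ROI are reported in a trailing
#' comment line.
#'
#' @param mapFile NIfTI path of a binary significance map.
#' @param atlasFile NIfTI path of the integer label volume.
#' @param namesFile TSV with columns label, name, atlas.
#' @param outFile output TSV path.
#' @param quiet suppress stage logging.
#' @return The report data.frame, invisibly.
#' @export
pipelineDescribe <- function(mapFile, atlasFile, namesFile, outFile,
                             quiet = FALSE) {
  map <- readThresholdedMap(mapFile)
  vol <- RNifti::readNifti(atlasFile)
  names <- utils::read.table(namesFile, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  atlas <- new("AtlasLabels",
               labelVolume = array(as.integer(round(vol)), dim = dim(vol)),
               names = names)
  rep <- atlasFractions(map, atlas)
  con <- file(outFile, "w")
  on.exit(close(con))
  utils::write.table(rep, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# n_outside_atlas\t%d", attr(rep, "n_outside")), con)
  if (!quiet)
    message(sprintf("describe: %d ROI(s) intersected, %d voxel(s) outside atlas",
                    nrow(rep), attr(rep, "n_outside")))
  invisible(rep)
}

# --- NIfTI map I/O -----------------------------------------------------

#' Write and read thresholded maps as NIfTI
#'
#' `writeThresholdedMap()` stores the binary significant volume with its
#' affine; the threshold metadata travels in a JSON sidecar
#' (`<path>.json`). `readThresholdedMap()` restores both (missing sidecar
#' gives NA metadata). `writeStatMapNifti()` writes a full-grid z volume
#' with 0 at untested voxels.
#'
#' @param map a [ThresholdedMap-class].
#' @param stat a [StatMap-class].
#' @param path NIfTI file path.
#' @return The path ([writeThresholdedMap()], [writeStatMapNifti()]) or a
#'   [ThresholdedMap-class] ([readThresholdedMap()]).
#' @export
writeThresholdedMap <- function(map, path) {
  writeVolume(map@significant, map@affine, path)
  meta <- list(z_cut = map@zCut, alpha_corrected = map@alphaCorrected,
               n_significant = map@nSignificant, provenance = map@provenance)
  writeRunManifest(meta, paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeThresholdedMap
#' @export
readThresholdedMap <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  sig <- array(as.numeric(img > 0.5), dim = dim(img))
  meta <- list(z_cut = NA_real_, alpha_corrected = NA_real_,
               provenance = list())
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  new("ThresholdedMap",
    significant = sig,
    zCut = as.numeric(meta$z_cut %||% NA_real_),
    alphaCorrected = as.numeric(meta$alpha_corrected %||% NA_real_),
    nSignificant = as.integer(sum(sig)),
    affine = aff,
    provenance = as.list(meta$provenance %||% list())
  )
}

#' @rdname writeThresholdedMap
#' @export
writeStatMapNifti <- function(stat, path) {
  arr <- array(0, dim = stat@gridShape)
  if (stat@nTests)
    arr[voxLinear(stat@voxels, stat@gridShape)] <- stat@zValues
  writeVolume(arr, stat@affine, path)
  invisible(path)
}

writeVolume <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- abs(diag(affine)[1:3])
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
}

writeRunManifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
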