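# Delimited-text interchange for cancellation sheets and score tables.

#' Write a cancellation sheet as tab-separated text
#'
#' One row per stimulus with columns `id`, `x_mm`, `y_mm`, `type`,
#' `marked` (0/1). The page extent is stored in a `# page` comment line so
#' sheets round-trip exactly.
#'
#' @param sheet a [CancellationSheet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSheet <- function(sheet, path) {
  st <- sheet@stimuli
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# page %g %g %g %g", sheet@pageXMin, sheet@pageXMax,
                     sheet@pageYMin, sheet@pageYMax), con)
  df <- data.frame(id = seq_len(nrow(st)), x_mm = st$x, y_mm = st$y,
                   type = st$type, marked = as.integer(st$marked))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cancellation sheet from tab-separated text
#'
#' Parses the format written by [writeSheet()]. Without a `# page` comment
#' the default landscape A4 extent (297 x 210 mm) is assumed. Malformed
#' rows are reported by row number.
#'
#' @param path input file path.
#' @return A [CancellationSheet-class].
#' @export
readSheet <- function(path) {
  lines <- readLines(path)
  page <- c(PAGE_X, PAGE_Y)
  pg <- grep("^# page ", lines, value = TRUE)
  if (length(pg))
    page <- as.numeric(strsplit(sub("^# page ", "", pg[1L]), " ")[[1L]])
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("x_mm", "y_mm", "type", "marked")
  if (!all(need %in% names(df)))
    stop("sheet file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  bad <- which(!df$type %in% c("complete", "left_gap", "right_gap") |
                 is.na(df$x_mm) | is.na(df$y_mm) | !df$marked %in% 0:1)
  if (length(bad))
    stop(sprintf("malformed stimulus row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  new("CancellationSheet",
    stimuli = data.frame(x = df$x_mm, y = df$y_mm, type = df$type,
                         marked = as.logical(df$marked),
                         stringsAsFactors = FALSE),
    pageXMin = page[1L], pageXMax = page[2L],
    pageYMin = page[3L], pageYMax = page[4L]
  )
}

#' Convert behavioural scores to a one-row data frame
#'
#' Columns match the pipeline scores table: patient_id, total_hits,
#' ego_coc, ego_asym, allo_score, allo_asym, labels
#' (semicolon-separated), excluded.
#'
#' @param scores a [BehaviouralScores-class].
#' @param patientId identifier for the row.
#' @return A one-row data.frame.
#' @export
scoresAsRow <- function(scores, patientId = NA_character_) {
  data.frame(
    patient_id = patientId,
    total_hits = scores@totalHits,
    ego_coc = scores@egoCoc,
    ego_asym = scores@egoAsymmetry,
    allo_score = scores@alloScore,
    allo_asym = scores@alloAsymmetry,
    labels = paste(scores@labels, collapse = ";"),
    excluded = scores@excluded,
    stringsAsFactors = FALSE
  )
}
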