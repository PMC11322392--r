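#' @include AllClasses.R
NULL

#' Write a frame sequence as multi-frame TIFF plus sidecar JSON
#'
#' Pixels go to an 8-bit multi-frame TIFF; the frame interval, pixel
#' spacing, sync events and metadata go to `<path>.json` next to it.
#'
#' @param sequence a [FrameSequence-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeFrameSequence <- function(sequence, path) {
  stopifnot(is(sequence, "FrameSequence"))
  n <- nFrames(sequence)
  frames <- lapply(seq_len(n), function(k) sequence@frames[, , k])
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  side <- list(frame_interval_s = sequence@frameIntervalS,
               pixel_spacing_mm = sequence@pixelSpacingMm,
               sync_events = sequence@syncEvents,
               metadata = sequence@metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame sequence written by [writeFrameSequence()]
#'
#' Accepts a multi-frame TIFF (with its `.json` sidecar) or a directory of
#' ordered single-frame TIFF/PNG files containing one sidecar JSON. All
#' frames must share one shape; the sidecar must provide the frame
#' interval.
#'
#' @param path TIFF file or directory.
#' @return a [FrameSequence-class].
#' @export
readFrameSequence <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) stop("no image files in ", path, call. = FALSE)
    frames <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
      else tiff::readTIFF(f)
    })
    sidecar <- list.files(path, pattern = "\\.json$", full.names = TRUE)[1L]
  } else {
    frames <- tiff::readTIFF(path, all = TRUE)
    sidecar <- paste0(path, ".json")
  }
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent frame shapes; first offender: frame ",
         which(shapes != shapes[1L])[1L], " (", shapes[shapes != shapes[1L]][1L],
         " vs ", shapes[1L], ")", call. = FALSE)
  if (is.na(sidecar) || !file.exists(sidecar))
    stop("sidecar JSON with frame metadata not found for ", path,
         call. = FALSE)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$frame_interval_s))
    stop("sidecar JSON lacks 'frame_interval_s'", call. = FALSE)
  arr <- array(0, c(dim(frames[[1L]])[1:2], length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  sync <- if (!is.null(side$sync_events) && length(side$sync_events))
    as.data.frame(side$sync_events) else data.frame()
  FrameSequence(arr, side$frame_interval_s,
                unlist(side$pixel_spacing_mm), sync,
                metadata = as.list(side$metadata))
}

#' Write ground-truth curves as CSV
#'
#' Columns: `frame`, `time_s`, then one column per muscle (TR, SP, Scap,
#' Scerv, MF) with true deformation in %.
#'
#' @param gt a [GroundTruth-class].
#' @param path output CSV path.
#' @export
writeGroundTruthCSV <- function(gt, path) {
  stopifnot(is(gt, "GroundTruth"))
  df <- data.frame(frame = seq_along(gt@times), time_s = gt@times)
  cur <- gt@curves
  colnames(cur) <- vapply(gt@layers, function(l) l@label, "")
  write.csv(cbind(df, cur), path, row.names = FALSE)
  invisible(path)
}

#' Write a tracked ROI as per-frame CSV
#'
#' Columns: `frame`, `time_s`, `length_mm`, `strain_increment`, `residual`,
#' `valid`. Coordinates follow the package convention (0-based pixel
#' indices scaled to mm), noted in the header comment.
#'
#' @param tracked a [TrackedROI-class].
#' @param path output CSV path.
#' @export
writeTrackedCSV <- function(tracked, path) {
  stopifnot(is(tracked, "TrackedROI"))
  df <- data.frame(frame = seq_along(tracked@lengthMm),
                   time_s = tracked@times, length_mm = tracked@lengthMm,
                   strain_increment = tracked@strainIncrement,
                   residual = tracked@residual, valid = tracked@valid)
  con <- file(path, "w")
  writeLines(sprintf("# muscle=%s; coordinates: 0-based px scaled to mm",
                     tracked@roi@muscle), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write deformation and rate curves as CSV
#'
#' Columns: `frame`, `time_s`, `deformation_percent`, `rate_percent_per_s`,
#' `valid`.
#'
#' @param curve a [DeformationCurve-class].
#' @param rate the matching [DeformationRateCurve-class].
#' @param path output CSV path.
#' @export
writeCurvesCSV <- function(curve, rate, path) {
  df <- data.frame(frame = seq_along(curve@times), time_s = curve@times,
                   deformation_percent = curve@values,
                   rate_percent_per_s = rate@values,
                   valid = curve@valid & rate@valid)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read the feature table with a JSON schema sidecar
#'
#' The CSV holds the metadata and 25 feature columns; the sidecar
#' (`<path>.schema.json`) documents column order, units (%*s for areas,
#' %/s for the RMS rate) and the sign convention (elongation positive).
#'
#' @param table a feature table.
#' @param path output CSV path.
#' @export
writeFeatureTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  schema <- list(
    columns = names(table),
    feature_columns = featureColumns(),
    units = list(total = "%*s", above = "%*s", below = "%*s",
                 diff = "%*s", raterms = "%/s"),
    conventions = paste("elongation positive; above/below refer to the 0%",
                        "line; diff = above - below; total = above + below"))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
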