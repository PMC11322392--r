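#' @include curves.R
NULL

#' Trapezoidal area of a uniformly sampled curve
#'
#' `A = (t/2) * (y1 + 2*y2 + ... + 2*y[n-1] + yn)` with `t` the time between
#' samples; the signed area, so lobes below zero subtract.
#'
#' @param values numeric samples.
#' @param sampleInterval uniform spacing `t > 0`.
#' @return signed area.
#' @export
trapezoidArea <- function(values, sampleInterval) {
  if (length(values) < 2L)
    stop("need at least 2 samples", call. = FALSE)
  stopifnot_scalar(sampleInterval, "sampleInterval", positive = TRUE)
  n <- length(values)
  inner <- if (n > 2L) sum(values[2:(n - 1L)]) else 0
  sampleInterval / 2 * (values[1L] + 2 * inner + values[n])
}

# trapezoid on an arbitrary (sorted) grid
trapezoidNonuniform <- function(times, values) {
  sum(diff(times) * (head(values, -1L) + values[-1L]) / 2)
}

#' Insert linear-interpolated zero crossings into a sampled curve
#'
#' For every sign change between consecutive samples, a sample `(t0, 0)` is
#' inserted at the root of the connecting line,
#' `t0 = t_i - y_i * (t_{i+1} - t_i) / (y_{i+1} - y_i)`. Samples that are
#' exactly zero are crossing points already; nothing is inserted around them.
#'
#' @param times,values numeric vectors of equal length.
#' @return list with augmented `times` and `values` and `inserted`, the
#'   logical mask of inserted samples.
#' @export
splitZeroCrossings <- function(times, values) {
  stopifnot(length(times) == length(values), all(is.finite(values)))
  n <- length(times)
  if (n < 2L)
    return(list(times = times, values = values, inserted = logical(n)))
  cross <- which(values[-n] * values[-1L] < 0)
  if (!length(cross))
    return(list(times = times, values = values, inserted = logical(n)))
  tCross <- times[cross] - values[cross] * (times[cross + 1L] - times[cross]) /
    (values[cross + 1L] - values[cross])
  ord <- order(c(times, tCross))
  newT <- c(times, tCross)[ord]
  newV <- c(values, numeric(length(tCross)))[ord]
  inserted <- c(logical(n), rep(TRUE, length(tCross)))[ord]
  list(times = newT, values = newV, inserted = inserted)
}

#' Decompose a deformation curve into areas split at the 0% line
#'
#' After inserting zero crossings ([splitZeroCrossings()]), trapezoidal
#' areas are accumulated separately over the non-negative and non-positive
#' runs of the augmented grid (non-uniform trapezoid): `areaAbove` is the
#' elongation area over the 0% line, `areaBelow` the magnitude of the
#' shortening area under it, `total` their sum and `difference` their
#' signed difference (equal to the signed trapezoid integral). The RMS
#' deformation rate is computed over the valid rate samples.
#'
#' Masked curve samples are excluded before decomposition (the remaining
#' samples keep their absolute times).
#'
#' @param curve a [DeformationCurve-class].
#' @param rate a [DeformationRateCurve-class] on the same time base, or
#'   `NULL` to derive it with [toRate()].
#' @return an [AreaDecomposition-class].
#' @export
decomposeAreas <- function(curve, rate = NULL) {
  stopifnot(is(curve, "DeformationCurve"))
  if (is.null(rate)) rate <- toRate(curve)
  stopifnot(is(rate, "DeformationRateCurve"))
  if (length(rate@times) != length(curve@times) ||
      any(abs(rate@times - curve@times) > 1e-9))
    stop("curve and rate must share the same time base", call. = FALSE)
  keep <- curve@valid
  if (sum(keep) < 2L)
    stop("need at least 2 valid samples", call. = FALSE)
  aug <- splitZeroCrossings(curve@times[keep], curve@values[keep])
  dt <- diff(aug$times)
  ybar <- (head(aug$values, -1L) + aug$values[-1L]) / 2
  seg <- dt * ybar                                   # signed trapezoid areas
  above <- sum(seg[ybar > 0])
  below <- -sum(seg[ybar < 0]) + 0   # + 0 normalizes IEEE negative zero
  rv <- rate@values[rate@valid]
  rms <- if (length(rv)) sqrt(mean(rv^2)) else NA_real_
  new("AreaDecomposition", areaAbove = above, areaBelow = below,
      total = above + below, difference = above - below, rateRms = rms,
      nValid = sum(rate@valid), muscle = curve@muscle)
}

#' Assemble the 25-variable feature table
#'
#' One row per subject x timepoint x direction with the 25 feature columns
#' (5 muscles x total / above / below / diff / raterms, in the fixed order
#' TR, SP, Scap, Scerv, MF) plus the metadata columns. The study's "under
#' curve" and "over curve" variables map to `below` (shortening area) and
#' `above` (elongation area); `diff = above - below`. Rows missing any of
#' the five muscles are rejected with a logged reason.
#'
#' @param decompositions data.frame with one row per muscle measurement:
#'   metadata columns (`subject`, `group`, `sex`, plus any of `age`,
#'   `wad_grade`, `timepoint`, `direction`), a `muscle` column, and columns
#'   `total`, `above`, `below`, `diff`, `raterms`.
#' @return the wide feature table; rejected rows are reported via `message`
#'   and recorded in the `"rejected"` attribute.
#' @export
buildFeatureTable <- function(decompositions) {
  need <- c("subject", "group", "sex", "muscle", FEATURE_STATS)
  if (!all(need %in% names(decompositions)))
    stop("missing columns: ",
         paste(setdiff(need, names(decompositions)), collapse = ", "),
         call. = FALSE)
  metaCols <- intersect(
    c("subject", "group", "sex", "age", "wad_grade", "timepoint", "direction"),
    names(decompositions))
  featCols <- as.vector(t(outer(MUSCLES, FEATURE_STATS, paste, sep = "_")))
  keyCols <- intersect(c("subject", "timepoint", "direction"), metaCols)
  key <- do.call(paste, c(decompositions[keyCols], sep = "\r"))
  rows <- list(); rejected <- character(0); i <- 0L
  for (k in unique(key)) {
    d <- decompositions[key == k, , drop = FALSE]
    if (!setequal(d$muscle, MUSCLES) || nrow(d) != 5L) {
      rejected <- c(rejected, sprintf(
        "row '%s' rejected: muscles [%s], need all of [%s]",
        gsub("\r", "/", k), paste(sort(d$muscle), collapse = ", "),
        paste(MUSCLES, collapse = ", ")))
      next
    }
    d <- d[match(MUSCLES, d$muscle), ]
    feats <- as.vector(t(as.matrix(d[, FEATURE_STATS])))
    i <- i + 1L
    rows[[i]] <- cbind(d[1L, metaCols, drop = FALSE],
                       as.data.frame(as.list(setNames(feats, featCols))))
  }
  for (r in rejected) message(r)
  out <- if (i) do.call(rbind, rows) else
    cbind(decompositions[0L, metaCols, drop = FALSE],
          as.data.frame(as.list(setNames(rep(NA_real_, 25L), featCols)))[0L, ])
  rownames(out) <- NULL
  bad <- !stats::complete.cases(out[, c("group", "sex")])
  if (any(bad)) stop("missing group/sex metadata", call. = FALSE)
  attr(out, "rejected") <- rejected
  out
}

#' Names of the 25 feature columns in canonical order
#' @return character(25).
#' @export
featureColumns <- function() {
  as.vector(t(outer(MUSCLES, FEATURE_STATS, paste, sep = "_")))
}

#' Summarize a tracked sequence into per-muscle area decompositions
#'
#' Runs the analysis segment extraction (tenth cycle by default), converts
#' to deformation relative to the segment start, differentiates, and
#' decomposes areas, for each tracked muscle.
#'
#' @param trackedList named list of [TrackedROI-class] (one per muscle).
#' @param sequence the [FrameSequence-class] they came from (for sync).
#' @param cycleIndex analyzed rotation cycle (default 10).
#' @param direction direction label for the curves.
#' @return data.frame, one row per muscle, columns `muscle` and the five
#'   statistics.
#' @export
summarizeTracked <- function(trackedList, sequence, cycleIndex = 10L,
                             direction = "") {
  seg <- segmentCycle(sequence, cycleIndex)
  rows <- lapply(names(trackedList), function(m) {
    tr <- trackedList[[m]]
    curve <- toDeformation(tr, referenceFrame = seg$start,
                           frames = seg$frames, direction = direction)
    dec <- decomposeAreas(curve)
    data.frame(muscle = m, total = dec@total, above = dec@areaAbove,
               below = dec@areaBelow, diff = dec@difference,
               raterms = dec@rateRms)
  })
  do.call(rbind, rows)
}
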