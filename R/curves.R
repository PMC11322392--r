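#' @include AllClasses.R
NULL

#' Convert tracked ROI lengths to a deformation curve
#'
#' Deformation is the percentage change of ROI length from its value at the
#' reference frame: `d_k = 100 * (L_k - L_ref) / L_ref`. Elongation is
#' positive, shortening negative. Invalid tracked frames stay masked.
#'
#' @param tracked a [TrackedROI-class], or a numeric vector of lengths (mm)
#'   with uniform sampling described by `frameIntervalS`.
#' @param referenceFrame 1-based index of the reference (rest) frame.
#' @param frames optional 1-based frame range to keep (e.g. from
#'   [segmentCycle()]); times are kept absolute.
#' @param frameIntervalS frame interval when `tracked` is a bare vector.
#' @param direction label stored on the curve.
#' @return a [DeformationCurve-class].
#' @export
toDeformation <- function(tracked, referenceFrame = 1L, frames = NULL,
                          frameIntervalS = NULL, direction = "") {
  if (is(tracked, "TrackedROI")) {
    L <- tracked@lengthMm
    valid <- tracked@valid
    times <- tracked@times
    muscle <- tracked@roi@muscle
  } else {
    L <- as.numeric(tracked)
    valid <- rep(TRUE, length(L))
    if (is.null(frameIntervalS))
      stop("frameIntervalS required for a bare length vector", call. = FALSE)
    times <- (seq_along(L) - 1L) * frameIntervalS
    muscle <- ""
  }
  if (referenceFrame < 1L || referenceFrame > length(L) ||
      !valid[referenceFrame])
    stop("invalid reference frame", call. = FALSE)
  Lref <- L[referenceFrame]
  vals <- 100 * (L - Lref) / Lref
  if (!is.null(frames)) {
    idx <- frames
    vals <- vals[idx]; valid <- valid[idx]; times <- times[idx]
  }
  new("DeformationCurve", times = times, values = vals,
      referenceLengthMm = Lref, valid = valid, muscle = muscle,
      direction = direction)
}

#' Differentiate a deformation curve
#'
#' Finite-difference deformation rate in %/s: central differences in the
#' interior, one-sided at the ends. A rate sample is masked whenever any
#' deformation sample its stencil touches is masked. Requires a uniform
#' frame interval.
#'
#' @param curve a [DeformationCurve-class].
#' @return a [DeformationRateCurve-class].
#' @export
toRate <- function(curve) {
  stopifnot(is(curve, "DeformationCurve"))
  n <- length(curve@values)
  if (sum(curve@valid) < 2L)
    stop("need at least 2 valid samples to differentiate", call. = FALSE)
  dtAll <- diff(curve@times)
  if (n > 2L && diff(range(dtAll)) > 1e-9 * max(dtAll))
    stop("non-uniform frame interval", call. = FALSE)
  dt <- dtAll[1L]
  y <- curve@values
  v <- numeric(n); ok <- logical(n)
  if (n >= 2L) {
    v[1L] <- (y[2L] - y[1L]) / dt
    v[n] <- (y[n] - y[n - 1L]) / dt
    ok[1L] <- curve@valid[1L] && curve@valid[2L]
    ok[n] <- curve@valid[n] && curve@valid[n - 1L]
  }
  if (n >= 3L) {
    i <- 2:(n - 1L)
    v[i] <- (y[i + 1L] - y[i - 1L]) / (2 * dt)
    ok[i] <- curve@valid[i - 1L] & curve@valid[i] & curve@valid[i + 1L]
  }
  new("DeformationRateCurve", times = curve@times, values = v, valid = ok,
      muscle = curve@muscle)
}

#' Locate one rotation cycle from the sync channel
#'
#' Returns the half-open frame interval `[start, stop)` of the requested
#' rotation cycle, delimited by the contact-switch start (midline) and stop
#' (back at midline) events. The analyzed segment always begins and ends at
#' sync events. The study analyzes the tenth rotation, hence the default.
#'
#' @param sequence a [FrameSequence-class] (or its `syncEvents` data.frame).
#' @param cycleIndex 1-based cycle number (default 10).
#' @return list with `start`, `stop` (1-based frame indices, stop exclusive)
#'   and `frames`, the integer vector `start:(stop - 1)`.
#' @export
segmentCycle <- function(sequence, cycleIndex = 10L) {
  ev <- if (is(sequence, "FrameSequence")) sequence@syncEvents else sequence
  need <- c("start", "stop")
  hit <- ev[ev$cycle == cycleIndex & ev$type %in% c("start", "reach", "stop"), ]
  if (!all(need %in% hit$type) || !"reach" %in% hit$type)
    stop(sprintf(paste0("incomplete sync triplet for cycle %d: found [%s]; ",
                        "%d cycles available"),
                 cycleIndex, paste(sort(unique(hit$type)), collapse = ", "),
                 if (nrow(ev)) max(ev$cycle) else 0L), call. = FALSE)
  start <- hit$frame[hit$type == "start"][1L]
  stop_ <- hit$frame[hit$type == "stop"][1L]
  list(start = start, stop = stop_, frames = start:(stop_ - 1L))
}
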