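#' @include AllClasses.R
NULL

#' Tracking configuration
#'
#' Parameters of the pyramidal window-based point tracker and of the strain
#' fit. Defaults: 8 px window half-size, 3 pyramid levels, 30 iterations,
#' 0.01 px convergence tolerance, at least half the points valid per frame,
#' ordinary (untrimmed) least squares.
#'
#' @param windowHalfsizePx per-axis window half-size in pixels (>= 2).
#' @param pyramidLevels number of pyramid levels.
#' @param maxIterations iteration cap per level.
#' @param convergenceTolPx update-norm threshold for convergence, px.
#' @param minValidFraction fraction of points that must track for a frame to
#'   be valid, in `(0, 1]`.
#' @param robustFit if `TRUE`, the strain fit trims the 20% largest-residual
#'   points once and refits.
#' @param maxResidual per-pixel mean squared window difference above which a
#'   point is flagged invalid (0-1 intensity scale).
#' @param minEigenvalue Shi-Tomasi gate: minimum eigenvalue of the gradient
#'   matrix per window pixel below which a point is untrackable.
#' @param maxInvalidRun number of consecutive invalid frames tolerated before
#'   tracking is declared lost.
#' @return list of class `TrackingConfig`.
#' @export
trackingConfig <- function(windowHalfsizePx = 8, pyramidLevels = 3,
                           maxIterations = 30, convergenceTolPx = 0.01,
                           minValidFraction = 0.5, robustFit = FALSE,
                           maxResidual = 0.02, minEigenvalue = 1e-3,
                           maxInvalidRun = 10) {
  stopifnot(windowHalfsizePx >= 2, minValidFraction > 0,
            minValidFraction <= 1)
  structure(list(windowHalfsizePx = as.integer(windowHalfsizePx),
                 pyramidLevels = as.integer(pyramidLevels),
                 maxIterations = as.integer(maxIterations),
                 convergenceTolPx = convergenceTolPx,
                 minValidFraction = minValidFraction,
                 robustFit = robustFit, maxResidual = maxResidual,
                 minEigenvalue = minEigenvalue,
                 maxInvalidRun = as.integer(maxInvalidRun)),
            class = "TrackingConfig")
}

#' Place a longitudinal ROI in the first frame
#'
#' Creates a straight ROI between two endpoints given in mm (depth, lateral)
#' with `nPoints` evenly spaced measuring points including the endpoints.
#' Endpoints must lie inside the frame with at least `marginPx` pixels to
#' every border (so tracking windows fit).
#'
#' @param sequence a [FrameSequence-class].
#' @param muscle muscle label.
#' @param endpointA,endpointB numeric(2) mm coordinates (depth, lateral).
#' @param nPoints number of measuring points (default 15).
#' @param marginPx border margin in pixels (default window half-size + 1).
#' @return a [RegionOfInterest-class].
#' @export
placeROI <- function(sequence, muscle, endpointA, endpointB, nPoints = 15,
                     marginPx = 9) {
  stopifnot(is(sequence, "FrameSequence"))
  sp <- sequence@pixelSpacingMm
  dimPx <- dim(sequence@frames)[1:2]
  for (e in list(endpointA, endpointB)) {
    px <- e / sp   # 0-based pixel coordinates
    if (any(px < marginPx) || px[1] > dimPx[1] - 1 - marginPx ||
        px[2] > dimPx[2] - 1 - marginPx)
      stop("ROI endpoint outside the frame or too close to the border",
           call. = FALSE)
  }
  len <- sqrt(sum((endpointA - endpointB)^2))
  tfrac <- seq(0, 1, length.out = nPoints)
  pts <- cbind(endpointA[1] + tfrac * (endpointB[1] - endpointA[1]),
               endpointA[2] + tfrac * (endpointB[2] - endpointA[2]))
  colnames(pts) <- c("depth", "lateral")
  new("RegionOfInterest", muscle = muscle,
      endpointA = as.numeric(endpointA), endpointB = as.numeric(endpointB),
      nPoints = as.integer(nPoints), nominalLengthMm = len, points = pts)
}

#' Track points between two frames
#'
#' Pyramidal window-based gradient-descent (Lucas-Kanade) tracking of a set
#' of points from `frameK` to `frameK1`. Each point's displacement minimizes
#' the local intensity SSD; points that leave the image, fail to converge,
#' sit on texture-free patches (Shi-Tomasi minimum-eigenvalue gate) or end
#' with a large residual are flagged invalid.
#'
#' @param frameK,frameK1 numeric matrices (the two frames).
#' @param pointsPx matrix n x 2 of 0-based (row, col) pixel positions in
#'   `frameK`.
#' @param config a [trackingConfig()].
#' @return data.frame with columns `drow`, `dcol` (px), `residual`,
#'   `converged`, `valid`.
#' @export
trackPair <- function(frameK, frameK1, pointsPx, config = trackingConfig()) {
  res <- cppLKTrack(frameK, frameK1, rbind(pointsPx),
                    config$windowHalfsizePx, config$pyramidLevels,
                    config$maxIterations, config$convergenceTolPx,
                    config$minEigenvalue, config$maxResidual)
  data.frame(drow = res[, 1], dcol = res[, 2], residual = res[, 3],
             converged = res[, 4] > 0, valid = res[, 6] > 0)
}

#' Least-squares linear strain fit along the ROI axis
#'
#' Fits `displacement = translation + strain * (position - centroid)` by
#' ordinary least squares over the valid measuring points; the slope is the
#' frame-to-frame strain increment. With `robust = TRUE` the 20% of points
#' with the largest absolute residuals are trimmed once and the line refit.
#'
#' @param positions numeric, point positions along the ROI axis (mm).
#' @param displacements numeric, point displacements along the axis (mm).
#' @param robust trim-and-refit flag.
#' @return list with `translation` (mm) and `strainIncrement`
#'   (dimensionless).
#' @export
fitLinearStrain <- function(positions, displacements, robust = FALSE) {
  keep <- is.finite(positions) & is.finite(displacements)
  positions <- positions[keep]; displacements <- displacements[keep]
  if (length(positions) < 2L || length(unique(positions)) < 2L)
    stop("degenerate strain fit: need >= 2 valid points with distinct positions",
         call. = FALSE)
  fit1 <- function(x, y) {
    xc <- x - mean(x)
    slope <- sum(xc * y) / sum(xc^2)
    # model is displacement = translation + slope * (x - ROI centroid), with
    # the centroid of the *used* points; translation follows from the means
    list(translation = mean(y) - slope * 0,
         slope = slope, centroid = mean(x))
  }
  f <- fit1(positions, displacements)
  if (robust && length(positions) >= 5L) {
    res <- displacements - (f$translation + f$slope * (positions - f$centroid))
    ord <- order(abs(res))
    keepN <- max(2L, floor(0.8 * length(positions)))
    idx <- sort(ord[seq_len(keepN)])
    f <- fit1(positions[idx], displacements[idx])
  }
  list(translation = f$translation, strainIncrement = f$slope)
}

#' Track an ROI through a whole sequence
#'
#' Chains [trackPair()] and [fitLinearStrain()] over consecutive frames.
#' After each step the measuring points are advected by the fitted linear
#' map (translation plus stretch about the point centroid along the ROI
#' axis; the mean lateral displacement is carried perpendicular to it) and
#' the ROI length is updated multiplicatively:
#' `L[k+1] = L[k] * (1 + strainIncrement)`. Frames where fewer than
#' `minValidFraction` of the points track are flagged invalid and carry the
#' previous length forward; a run of invalid frames longer than
#' `maxInvalidRun` aborts with a tracking-lost error.
#'
#' @param sequence a [FrameSequence-class].
#' @param roi a [RegionOfInterest-class] placed in the first frame.
#' @param config a [trackingConfig()].
#' @return a [TrackedROI-class].
#' @export
trackSequence <- function(sequence, roi, config = trackingConfig()) {
  stopifnot(is(sequence, "FrameSequence"), is(roi, "RegionOfInterest"))
  sp <- sequence@pixelSpacingMm
  nF <- nFrames(sequence)
  nP <- roi@nPoints
  axis <- (roi@endpointB - roi@endpointA)
  axis <- axis / sqrt(sum(axis^2))            # unit vector (depth, lateral)
  perp <- c(-axis[2], axis[1])

  pos <- array(NA_real_, c(nP, 2L, nF))
  pos[, , 1L] <- roi@points
  lengthMm <- numeric(nF); lengthMm[1L] <- roi@nominalLengthMm
  strainInc <- numeric(nF)
  residual <- rep(NA_real_, nF)
  valid <- rep(TRUE, nF)
  cur <- roi@points                            # mm (depth, lateral)
  invalidRun <- 0L

  if (nF >= 2L) for (k in seq_len(nF - 1L)) {
    ptsPx <- cbind(cur[, 1] / sp[1], cur[, 2] / sp[2])
    tr <- trackPair(sequence@frames[, , k], sequence@frames[, , k + 1L],
                    ptsPx, config)
    ok <- tr$valid
    if (k == 1L && !any(ok))
      stop("tracking failed on the first frame pair", call. = FALSE)
    residual[k + 1L] <- mean(tr$residual[ok], na.rm = TRUE)
    if (mean(ok) < config$minValidFraction || sum(ok) < 2L) {
      valid[k + 1L] <- FALSE
      invalidRun <- invalidRun + 1L
      if (invalidRun > config$maxInvalidRun)
        stop(sprintf("tracking lost: %d consecutive invalid frames at frame %d",
                     invalidRun, k + 1L), call. = FALSE)
      lengthMm[k + 1L] <- lengthMm[k]          # carry forward, flagged
      pos[, , k + 1L] <- cur
      next
    }
    invalidRun <- 0L
    dispMm <- cbind(tr$drow * sp[1], tr$dcol * sp[2])
    s <- drop((cur - matrix(colMeans(cur), nP, 2, byrow = TRUE)) %*% axis)
    d <- drop(dispMm %*% axis)
    fit <- fitLinearStrain(s[ok], d[ok], robust = config$robustFit)
    dPerp <- mean(drop(dispMm[ok, , drop = FALSE] %*% perp))
    centroid <- colMeans(cur)
    adv <- (fit$translation + fit$strainIncrement * s)
    cur <- cur + outer(adv, axis) + matrix(dPerp * perp, nP, 2, byrow = TRUE)
    # re-center: centroid moves by translation along axis + perp drift
    strainInc[k + 1L] <- fit$strainIncrement
    lengthMm[k + 1L] <- lengthMm[k] * (1 + fit$strainIncrement)
    pos[, , k + 1L] <- cur
  }
  new("TrackedROI", roi = roi, positions = pos, lengthMm = lengthMm,
      strainIncrement = strainInc, residual = residual, valid = valid,
      times = (seq_len(nF) - 1L) * sequence@frameIntervalS,
      frameIntervalS = sequence@frameIntervalS)
}

#' Default ROI set for the five-layer phantom
#'
#' One 15 mm ROI per muscle layer, horizontal (along the fibers) at the
#' layer's center depth, laterally centered.
#'
#' @param sequence a [FrameSequence-class].
#' @param layers the layer list used to simulate it.
#' @param lengthMm ROI length (default 15).
#' @param nPoints measuring points per ROI.
#' @return named list of [RegionOfInterest-class], one per muscle.
#' @export
defaultROIs <- function(sequence, layers = defaultLayers(), lengthMm = 15,
                        nPoints = 15) {
  extent <- dim(sequence@frames)[1:2] * sequence@pixelSpacingMm
  centerLat <- extent[2] / 2
  rois <- lapply(layers, function(l) {
    d <- mean(l@depthRange)
    placeROI(sequence, l@label,
             c(d, centerLat - lengthMm / 2), c(d, centerLat + lengthMm / 2),
             nPoints = nPoints)
  })
  names(rois) <- vapply(layers, function(l) l@label, "")
  rois
}
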