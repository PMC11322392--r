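#' @include AllClasses.R
NULL

#' Accessors for SpeckleStrain containers
#'
#' Standard accessor generics: `frames()` returns the pixel array of a
#' [FrameSequence-class]; `nFrames()` its frame count; `frameInterval()` the
#' frame interval in seconds; `pixelSpacing()` the (axial, lateral) mm per
#' pixel; `syncEvents()` the contact-switch event table; `roiLength()` the
#' per-frame tracked ROI length (mm); `curveValues()` and `curveTimes()` the
#' samples of a deformation or rate curve.
#'
#' @param x an object of the documented classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("syncEvents", function(x) standardGeneric("syncEvents"))
#' @rdname accessors
#' @export
setGeneric("roiLength", function(x) standardGeneric("roiLength"))
#' @rdname accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("trueCurves", function(x) standardGeneric("trueCurves"))

#' @rdname accessors
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSequence", function(x) dim(x@frames)[3L])
#' @rdname accessors
#' @export
setMethod("frameInterval", "FrameSequence", function(x) x@frameIntervalS)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "FrameSequence", function(x) x@pixelSpacingMm)
#' @rdname accessors
#' @export
setMethod("syncEvents", "FrameSequence", function(x) x@syncEvents)
#' @rdname accessors
#' @export
setMethod("roiLength", "TrackedROI", function(x) x@lengthMm)
#' @rdname accessors
#' @export
setMethod("validMask", "TrackedROI", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("curveValues", "DeformationCurve", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("curveTimes", "DeformationCurve", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("validMask", "DeformationCurve", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("curveValues", "DeformationRateCurve", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("curveTimes", "DeformationRateCurve", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("validMask", "DeformationRateCurve", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("trueCurves", "GroundTruth", function(x) x@curves)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames of %d x %d px, %.1f fps\n",
              d[3], d[1], d[2], 1 / object@frameIntervalS))
  cat(sprintf("  pixel spacing %.3f x %.3f mm, %d sync events\n",
              object@pixelSpacingMm[1], object@pixelSpacingMm[2],
              nrow(object@syncEvents)))
})

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf("RegionOfInterest '%s': %.2f mm, %d measuring points\n",
              object@muscle, object@nominalLengthMm, object@nPoints))
})

setMethod("show", "TrackedROI", function(object) {
  n <- length(object@lengthMm)
  cat(sprintf("TrackedROI '%s': %d frames, %d valid\n",
              object@roi@muscle, n, sum(object@valid)))
  if (n)
    cat(sprintf("  length %.2f -> %.2f mm (range %.2f-%.2f)\n",
                object@lengthMm[1], object@lengthMm[n],
                min(object@lengthMm), max(object@lengthMm)))
})

setMethod("show", "DeformationCurve", function(object) {
  cat(sprintf("DeformationCurve '%s' (%s): %d samples, range %.2f%% to %.2f%%\n",
              object@muscle, object@direction, length(object@values),
              min(object@values[object@valid]),
              max(object@values[object@valid])))
})

setMethod("show", "AreaDecomposition", function(object) {
  cat(sprintf(paste0("AreaDecomposition '%s': above %.3f, below %.3f, ",
                     "total %.3f, diff %.3f %%*s; RMS rate %.3f %%/s\n"),
              object@muscle, object@areaAbove, object@areaBelow,
              object@total, object@difference, object@rateRms))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d frames x %d layers, peak |deformation| %.2f%%\n",
              nrow(object@curves), ncol(object@curves),
              max(abs(object@curves))))
})
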