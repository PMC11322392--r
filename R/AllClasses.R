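#' @include SpeckleStrain-package.R
NULL

# ---------------------------------------------------------------- LayerSpec

#' Muscle layer specification for the synthetic phantom
#'
#' A `LayerSpec` describes one muscle layer of the phantom: its label, its
#' depth extent below the transducer face, the peak cyclic strain it
#' undergoes (signed, elongation positive), a phase offset within the
#' rotation cycle and the between-subject SD of its amplitude.
#'
#' @slot label character, one of [MUSCLES].
#' @slot depthRange numeric(2), depth interval in mm from the top of the image.
#' @slot strainAmplitude numeric, peak deformation in % per cycle (signed).
#' @slot phaseOffset numeric, fraction of a cycle in `[0, 1)`.
#' @slot noiseSd numeric, per-subject amplitude jitter SD in percentage points.
#'
#' @export
setClass("LayerSpec",
  representation(label = "character", depthRange = "numeric",
                 strainAmplitude = "numeric", phaseOffset = "numeric",
                 noiseSd = "numeric"))

setValidity("LayerSpec", function(object) {
  msg <- NULL
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single string")
  if (length(object@depthRange) != 2L || diff(object@depthRange) <= 0)
    msg <- c(msg, "depthRange must be an increasing interval (mm)")
  if (!is.finite(object@strainAmplitude))
    msg <- c(msg, "strainAmplitude must be finite")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @param label,depthRange,strainAmplitude,phaseOffset,noiseSd see slots.
#' @rdname LayerSpec-class
#' @export
LayerSpec <- function(label, depthRange, strainAmplitude = 0,
                      phaseOffset = 0, noiseSd = 0) {
  new("LayerSpec", label = label, depthRange = as.numeric(depthRange),
      strainAmplitude = as.numeric(strainAmplitude),
      phaseOffset = as.numeric(phaseOffset), noiseSd = as.numeric(noiseSd))
}

#' Default five-layer dorsal neck geometry
#'
#' Five stacked layers in the top-to-bottom order TR, SP, Scap, Scerv, MF
#' (superficial trapezius at the top), each roughly 4.6 mm thick with a
#' 0.4 mm fascial gap, spanning 2-27 mm depth.
#'
#' @param amplitudes named or positional numeric(5), peak strain % per layer.
#' @param noiseSd per-subject amplitude jitter SD (recycled).
#' @return list of five [LayerSpec-class] objects.
#' @export
defaultLayers <- function(amplitudes = c(TR = 3.5, SP = 4, Scap = 5.5,
                                         Scerv = 7, MF = 7.5),
                          noiseSd = 0) {
  if (!is.null(names(amplitudes))) amplitudes <- amplitudes[MUSCLES]
  stopifnot(length(amplitudes) == 5L)
  noiseSd <- rep_len(noiseSd, 5L)
  lo <- c(2, 7, 12, 17, 22)
  hi <- lo + 4.6
  lapply(seq_len(5L), function(i)
    LayerSpec(MUSCLES[i], c(lo[i], hi[i]), amplitudes[[i]], 0, noiseSd[i]))
}

# validate a list of layers: disjoint, ordered top-to-bottom
checkLayers <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  lapply(layers, validObject)
  rng <- t(vapply(layers, function(l) l@depthRange, numeric(2)))
  if (is.unsorted(as.vector(t(rng)), strictly = TRUE))
    stop("layer depth ranges must be disjoint and ordered top-to-bottom",
         call. = FALSE)
  invisible(layers)
}

# ---------------------------------------------------------------- MotionModel

#' Cyclic rotation motion model
#'
#' Prescribes the paced neck-rotation task: a number of identical
#' out-and-back cycles at a fixed period, optionally preceded by motionless
#' rest frames. The within-cycle waveform is either a raised cosine
#' (`"raisedcos"`, one-signed, peak at mid-cycle) or a biphasic shape
#' (`"biphasic"`, elongation lobe followed by a shortening undershoot).
#' An optional global sinusoidal translation (mm, axial/lateral) superimposes
#' rigid motion, e.g. probe sway.
#'
#' @slot nCycles integer, number of rotation cycles (default 10).
#' @slot cyclePeriodS numeric, seconds per out-and-back cycle (default 2).
#' @slot restFrames integer, motionless frames prepended (default 25).
#' @slot waveform `"raisedcos"` or `"biphasic"`.
#' @slot undershoot numeric, shortening-lobe amplitude as a fraction of the
#'   elongation lobe, used by `"biphasic"` (default 0.3).
#' @slot translationMm numeric(2), amplitude of rigid sinusoidal translation
#'   (axial, lateral) in mm (default 0, 0).
#'
#' @export
setClass("MotionModel",
  representation(nCycles = "integer", cyclePeriodS = "numeric",
                 restFrames = "integer", waveform = "character",
                 undershoot = "numeric", translationMm = "numeric"))

setValidity("MotionModel", function(object) {
  msg <- NULL
  if (object@nCycles < 1L) msg <- c(msg, "nCycles must be >= 1")
  if (object@cyclePeriodS <= 0) msg <- c(msg, "cyclePeriodS must be > 0")
  if (object@restFrames < 0L) msg <- c(msg, "restFrames must be >= 0")
  if (!object@waveform %in% c("raisedcos", "biphasic"))
    msg <- c(msg, "waveform must be 'raisedcos' or 'biphasic'")
  if (length(object@translationMm) != 2L)
    msg <- c(msg, "translationMm must have length 2")
  if (is.null(msg)) TRUE else msg
})

#' @param nCycles,cyclePeriodS,restFrames,waveform,undershoot,translationMm
#'   see slots.
#' @rdname MotionModel-class
#' @export
MotionModel <- function(nCycles = 10, cyclePeriodS = 2.0, restFrames = 25,
                        waveform = "raisedcos", undershoot = 0.3,
                        translationMm = c(0, 0)) {
  new("MotionModel", nCycles = as.integer(nCycles),
      cyclePeriodS = as.numeric(cyclePeriodS),
      restFrames = as.integer(restFrames), waveform = waveform,
      undershoot = as.numeric(undershoot),
      translationMm = as.numeric(translationMm))
}

# ---------------------------------------------------------------- SceneConfig

#' Imaging scene configuration for the speckle phantom
#'
#' Emulates the B-mode acquisition geometry: image raster, physical pixel
#' spacing, frame rate, scatterer density, a Gaussian point-spread function
#' and additive sensor noise. No acoustic physics is modelled; the phantom
#' exists to carry a known deformation field under a realistic-looking
#' speckle texture.
#'
#' @slot imageSize integer(2), rows x cols in pixels.
#' @slot pixelSpacingMm numeric(2), (axial, lateral) mm per pixel.
#' @slot frameRateHz numeric, frames per second (default 50).
#' @slot speckleDensity numeric, scatterers per square mm.
#' @slot pointSpreadMm numeric(2), Gaussian PSF sigma (axial, lateral) in mm.
#' @slot noiseSd numeric, additive noise SD on the 0-1 intensity scale.
#' @slot noiseMode `"static"` (one frozen sensor-noise field shared by all
#'   frames) or `"temporal"` (fresh noise per frame).
#' @slot seed integer master seed; identical seeds give bit-identical output.
#'
#' @export
setClass("SceneConfig",
  representation(imageSize = "integer", pixelSpacingMm = "numeric",
                 frameRateHz = "numeric", speckleDensity = "numeric",
                 pointSpreadMm = "numeric", noiseSd = "numeric",
                 noiseMode = "character", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- NULL
  if (length(object@imageSize) != 2L || any(object@imageSize <= 0L))
    msg <- c(msg, "imageSize must be two positive integers")
  if (length(object@pixelSpacingMm) != 2L || any(object@pixelSpacingMm <= 0))
    msg <- c(msg, "pixelSpacingMm must be two positive numbers")
  if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be > 0")
  if (object@speckleDensity < 0) msg <- c(msg, "speckleDensity must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@noiseMode %in% c("static", "temporal"))
    msg <- c(msg, "noiseMode must be 'static' or 'temporal'")
  if (is.null(msg)) TRUE else msg
})

#' @param imageSize,pixelSpacingMm,frameRateHz,speckleDensity,pointSpreadMm
#'   see slots.
#' @param noiseSd,noiseMode,seed see slots.
#' @rdname SceneConfig-class
#' @export
SceneConfig <- function(imageSize = c(200L, 256L),
                        pixelSpacingMm = c(0.15, 0.15),
                        frameRateHz = 50, speckleDensity = 25,
                        pointSpreadMm = c(0.12, 0.25), noiseSd = 0.02,
                        noiseMode = "static", seed = 1L) {
  if (any(imageSize <= 0))
    stop("invalid SceneConfig: image size must be positive", call. = FALSE)
  new("SceneConfig", imageSize = as.integer(imageSize),
      pixelSpacingMm = as.numeric(pixelSpacingMm),
      frameRateHz = as.numeric(frameRateHz),
      speckleDensity = as.numeric(speckleDensity),
      pointSpreadMm = rep_len(as.numeric(pointSpreadMm), 2L),
      noiseSd = as.numeric(noiseSd), noiseMode = noiseMode,
      seed = as.integer(seed))
}

# -------------------------------------------------------------- FrameSequence

#' An ultrasound-like video with acquisition metadata
#'
#' Frames are stored as a rows x cols x nFrames array of intensities in
#' `[0, 1]` (8-bit quantized by the simulator). Pixel coordinates are
#' 0-based (row, col) indices; physical coordinates are mm with depth =
#' row * axial spacing and lateral = col * lateral spacing. The sync channel
#' records the contact-switch events (cycle start at midline, 20-degree
#' reach, stop back at midline) as 1-based frame indices.
#'
#' @slot frames numeric array, rows x cols x nFrames.
#' @slot frameIntervalS numeric, seconds between frames.
#' @slot pixelSpacingMm numeric(2), (axial, lateral) mm per pixel.
#' @slot syncEvents data.frame with columns `frame`, `time_s`,
#'   `type` (start/reach/stop) and `cycle`.
#' @slot metadata list of free-form provenance fields.
#'
#' @export
setClass("FrameSequence",
  representation(frames = "array", frameIntervalS = "numeric",
                 pixelSpacingMm = "numeric", syncEvents = "data.frame",
                 metadata = "list"))

setValidity("FrameSequence", function(object) {
  msg <- NULL
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3-D array (rows x cols x nFrames)")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be > 0")
  if (length(object@pixelSpacingMm) != 2L || any(object@pixelSpacingMm <= 0))
    msg <- c(msg, "pixelSpacingMm must be two positive numbers")
  if (nrow(object@syncEvents) &&
      (any(object@syncEvents$frame < 1) ||
       any(object@syncEvents$frame > dim(object@frames)[3])))
    msg <- c(msg, "sync events outside the frame range")
  if (is.null(msg)) TRUE else msg
})

FrameSequence <- function(frames, frameIntervalS, pixelSpacingMm,
                          syncEvents = data.frame(), metadata = list()) {
  new("FrameSequence", frames = frames,
      frameIntervalS = as.numeric(frameIntervalS),
      pixelSpacingMm = as.numeric(pixelSpacingMm),
      syncEvents = syncEvents, metadata = metadata)
}

# ---------------------------------------------------------------- GroundTruth

#' Exact ground truth carried alongside a simulated sequence
#'
#' Stores the per-layer true deformation curves (% vs frame), the per-frame
#' layer strains and rigid translation actually used to advect the
#' scatterers, and the geometry needed to evaluate the displacement field at
#' any point. This is bookkeeping of the transform that generated the video,
#' not a re-estimate.
#'
#' @slot curves matrix nFrames x nLayers, true deformation in %.
#' @slot layerStrain matrix nFrames x nLayers, dimensionless strain
#'   (`curves / 100`).
#' @slot translationMm matrix nFrames x 2, rigid (axial, lateral) offset.
#' @slot times numeric, frame times in seconds.
#' @slot layers list of [LayerSpec-class].
#' @slot centerLateralMm numeric, lateral coordinate about which stretch is
#'   applied.
#' @slot edgeMm numeric, blend margin of the through-depth strain profile.
#'
#' @export
setClass("GroundTruth",
  representation(curves = "matrix", layerStrain = "matrix",
                 translationMm = "matrix", times = "numeric",
                 layers = "list", centerLateralMm = "numeric",
                 edgeMm = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- NULL
  if (nrow(object@curves) && any(abs(object@curves[1L, ]) > 1e-12))
    msg <- c(msg, "deformation at frame 0 must be 0")
  if (!identical(dim(object@curves), dim(object@layerStrain)))
    msg <- c(msg, "curves and layerStrain must have identical shape")
  if (is.null(msg)) TRUE else msg
})

# ----------------------------------------------------------- RegionOfInterest

#' A longitudinal region of interest along a muscle's fiber direction
#'
#' A straight 15 mm segment (by default) between two endpoints given in mm
#' (depth, lateral), carrying `nPoints` evenly spaced measuring points
#' including the endpoints.
#'
#' @slot muscle character label.
#' @slot endpointA,endpointB numeric(2), frame-0 coordinates in mm
#'   (depth, lateral).
#' @slot nPoints integer, number of measuring points (default 15).
#' @slot nominalLengthMm numeric, |A - B| in mm.
#' @slot points matrix nPoints x 2, measuring-point coordinates in mm.
#'
#' @export
setClass("RegionOfInterest",
  representation(muscle = "character", endpointA = "numeric",
                 endpointB = "numeric", nPoints = "integer",
                 nominalLengthMm = "numeric", points = "matrix"))

setValidity("RegionOfInterest", function(object) {
  msg <- NULL
  if (object@nominalLengthMm <= 0) msg <- c(msg, "nominalLengthMm must be > 0")
  len <- sqrt(sum((object@endpointA - object@endpointB)^2))
  if (abs(len - object@nominalLengthMm) > 1e-9)
    msg <- c(msg, "|A - B| must equal nominalLengthMm within 1e-9")
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (nrow(object@points) != object@nPoints)
    msg <- c(msg, "points must have nPoints rows")
  if (is.null(msg)) TRUE else msg
})

# ------------------------------------------------------------------ TrackedROI

#' Frame-by-frame tracking result for one ROI
#'
#' Per-frame measuring-point positions, ROI lengths accumulated
#' multiplicatively from the fitted strain increments, fit residuals and
#' validity flags. On valid frames
#' `length[k+1] = length[k] * (1 + strainIncrement[k+1])`.
#'
#' @slot roi the tracked [RegionOfInterest-class].
#' @slot positions array nPoints x 2 x nFrames, point coordinates in mm.
#' @slot lengthMm numeric, per-frame ROI length (mm).
#' @slot strainIncrement numeric, frame-to-frame strain (dimensionless;
#'   entry k is the increment from frame k-1 to k, 0 at the first frame).
#' @slot residual numeric, mean per-pixel SSD of the point-tracking windows.
#' @slot valid logical, per-frame validity.
#' @slot times numeric, frame times (s).
#' @slot frameIntervalS numeric.
#'
#' @export
setClass("TrackedROI",
  representation(roi = "RegionOfInterest", positions = "array",
                 lengthMm = "numeric", strainIncrement = "numeric",
                 residual = "numeric", valid = "logical", times = "numeric",
                 frameIntervalS = "numeric"))

setValidity("TrackedROI", function(object) {
  msg <- NULL
  n <- length(object@lengthMm)
  if (length(object@valid) != n || length(object@strainIncrement) != n ||
      length(object@times) != n)
    msg <- c(msg, "per-frame slots must have equal length")
  if (n > 0) {
    if (abs(object@lengthMm[1L] - object@roi@nominalLengthMm) > 1e-9)
      msg <- c(msg, "frame-0 length must equal nominalLengthMm")
    if (any(object@lengthMm[object@valid] <= 0))
      msg <- c(msg, "lengths must be > 0 on valid frames")
  }
  if (is.null(msg)) TRUE else msg
})

# ----------------------------------------------------- Deformation curve types

#' A deformation curve in percent of reference ROI length
#'
#' `values` holds 100 * (L - L_ref) / L_ref; elongation positive, shortening
#' negative, zero at the reference frame. Masked (invalid) samples carry
#' `valid = FALSE`.
#'
#' @slot times numeric, seconds.
#' @slot values numeric, % deformation.
#' @slot referenceLengthMm numeric.
#' @slot valid logical mask.
#' @slot muscle,direction character labels ("" when not applicable).
#'
#' @export
setClass("DeformationCurve",
  representation(times = "numeric", values = "numeric",
                 referenceLengthMm = "numeric", valid = "logical",
                 muscle = "character", direction = "character"))

setValidity("DeformationCurve", function(object) {
  msg <- NULL
  if (length(object@values) != length(object@times) ||
      length(object@valid) != length(object@times))
    msg <- c(msg, "times, values and valid must have equal length")
  if (any(!is.finite(object@values[object@valid])))
    msg <- c(msg, "values must be finite on valid samples")
  if (is.null(msg)) TRUE else msg
})

#' A deformation-rate curve in percent per second
#'
#' Time derivative of a [DeformationCurve-class], central differences in the
#' interior and one-sided at the ends; masks propagate from the samples a
#' difference touches.
#'
#' @slot times numeric, seconds.
#' @slot values numeric, %/s.
#' @slot valid logical mask.
#' @slot muscle character label.
#'
#' @export
setClass("DeformationRateCurve",
  representation(times = "numeric", values = "numeric", valid = "logical",
                 muscle = "character"))

setValidity("DeformationRateCurve", function(object) {
  if (length(object@values) != length(object@times) ||
      length(object@valid) != length(object@times))
    "times, values and valid must have equal length" else TRUE
})

# ----------------------------------------------------------- AreaDecomposition

#' Trapezoidal area decomposition of a deformation curve
#'
#' Areas of the curve split at the 0% line (crossings inserted by linear
#' interpolation): `areaAbove` (elongation, %*s), `areaBelow` (magnitude of
#' the shortening area, %*s), their `total` and `difference`, plus the
#' root-mean-square deformation rate (%/s).
#'
#' @slot areaAbove,areaBelow,total,difference numeric, %*s.
#' @slot rateRms numeric, %/s.
#' @slot nValid integer, number of valid samples used.
#' @slot muscle character label.
#'
#' @export
setClass("AreaDecomposition",
  representation(areaAbove = "numeric", areaBelow = "numeric",
                 total = "numeric", difference = "numeric",
                 rateRms = "numeric", nValid = "integer",
                 muscle = "character"))

setValidity("AreaDecomposition", function(object) {
  msg <- NULL
  if (object@areaAbove < 0 || object@areaBelow < 0)
    msg <- c(msg, "areaAbove and areaBelow must be >= 0")
  if (abs(object@total - (object@areaAbove + object@areaBelow)) > 1e-9)
    msg <- c(msg, "total must equal areaAbove + areaBelow")
  if (object@rateRms < 0) msg <- c(msg, "rateRms must be >= 0")
  if (is.null(msg)) TRUE else msg
})

# ---------------------------------------------------------------- CohortConfig

#' Simulated cohort configuration
#'
#' Encodes the case-control effect structure: per (group, muscle, direction)
#' mean strain amplitudes, between-subject variability, optional follow-up
#' amplitude changes for the WAD group, and a master seed. The default
#' effect map plants reduced deformation of the three deepest layers in the
#' WAD group for right rotation only, with partial normalization at
#' follow-up.
#'
#' @slot nPerGroup integer, subjects per group.
#' @slot groupEffects data.frame with columns `group`, `direction`, `muscle`,
#'   `amplitude` (mean peak strain %).
#' @slot betweenSubjectSd numeric, total SD of a subject's per-muscle
#'   amplitude (percentage points).
#' @slot subjectCorrelation numeric in `[0, 1]`, share of that variance common
#'   to all muscles of a subject (compound-symmetry weight).
#' @slot timepoints character, e.g. `c("baseline", "followup")`.
#' @slot followupEffects named numeric, per-muscle amplitude change applied to
#'   the WAD group at follow-up.
#' @slot seed integer master seed.
#'
#' @export
setClass("CohortConfig",
  representation(nPerGroup = "integer", groupEffects = "data.frame",
                 betweenSubjectSd = "numeric", subjectCorrelation = "numeric",
                 timepoints = "character", followupEffects = "numeric",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- NULL
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  if (object@betweenSubjectSd < 0) msg <- c(msg, "betweenSubjectSd must be >= 0")
  if (object@subjectCorrelation < 0 || object@subjectCorrelation > 1)
    msg <- c(msg, "subjectCorrelation must be in [0, 1]")
  need <- c("group", "direction", "muscle", "amplitude")
  if (!all(need %in% names(object@groupEffects)))
    msg <- c(msg, "groupEffects needs columns group, direction, muscle, amplitude")
  if (is.null(msg)) TRUE else msg
})

#' Default group-effect map emulating the study's qualitative findings
#'
#' Controls share one amplitude profile in both rotation directions; the WAD
#' group has the three deepest muscles (Scap, Scerv, MF) reduced by
#' `deepDeficit` percentage points in right rotation (the most painful side)
#' and matches controls in left rotation.
#'
#' @param deepDeficit amplitude reduction (percentage points) planted in the
#'   WAD deep muscles for right rotation.
#' @return data.frame usable as the `groupEffects` slot of
#'   [CohortConfig-class].
#' @export
defaultGroupEffects <- function(deepDeficit = 2.0) {
  base <- c(TR = 3.5, SP = 4, Scap = 5.5, Scerv = 7, MF = 7.5)
  grid <- expand.grid(group = c("WAD", "control"),
                      direction = c("right", "left"),
                      muscle = MUSCLES, stringsAsFactors = FALSE)
  grid$amplitude <- base[grid$muscle]
  hit <- grid$group == "WAD" & grid$direction == "right" &
    grid$muscle %in% c("Scap", "Scerv", "MF")
  grid$amplitude[hit] <- grid$amplitude[hit] - deepDeficit
  grid
}

#' @param nPerGroup,groupEffects,betweenSubjectSd,subjectCorrelation see slots.
#' @param timepoints,followupEffects,seed see slots.
#' @rdname CohortConfig-class
#' @export
CohortConfig <- function(nPerGroup = 34,
                         groupEffects = defaultGroupEffects(),
                         betweenSubjectSd = 1.5, subjectCorrelation = 0.5,
                         timepoints = "baseline",
                         followupEffects = c(TR = 0, SP = 0, Scap = 1.5,
                                             Scerv = 1.5, MF = 1.5),
                         seed = 1L) {
  new("CohortConfig", nPerGroup = as.integer(nPerGroup),
      groupEffects = groupEffects,
      betweenSubjectSd = as.numeric(betweenSubjectSd),
      subjectCorrelation = as.numeric(subjectCorrelation),
      timepoints = timepoints, followupEffects = followupEffects,
      seed = as.integer(seed))
}
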