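#' @include AllClasses.R
NULL

# Within-cycle waveform, u in [0, 1); both shapes start and end at 0.
cycleWaveform <- function(u, waveform, undershoot = 0.3) {
  u <- u %% 1
  switch(waveform,
    raisedcos = 0.5 * (1 - cos(2 * pi * u)),
    biphasic  = {
      w <- sin(2 * pi * u)
      ifelse(w < 0, undershoot * w, w)
    },
    stop("unknown waveform: ", waveform))
}

# Per-frame dimensionless layer strain matrix (nFrames x nLayers) and times.
motionTimeline <- function(layers, motion, frameRateHz) {
  dt <- 1 / frameRateHz
  nActive <- round(motion@nCycles * motion@cyclePeriodS * frameRateHz)
  nFrames <- motion@restFrames + nActive + 1L
  times <- (seq_len(nFrames) - 1L) * dt
  k <- seq_len(nFrames) - 1L
  uAll <- (k - motion@restFrames) * dt / motion@cyclePeriodS
  active <- k >= motion@restFrames & uAll <= motion@nCycles
  S <- matrix(0, nFrames, length(layers))
  for (j in seq_along(layers)) {
    l <- layers[[j]]
    w <- numeric(nFrames)
    # waveform is cyclic; the final frame closes the last cycle at exactly 0
    uj <- (uAll[active] - l@phaseOffset)
    w[active] <- cycleWaveform(uj, motion@waveform, motion@undershoot)
    # exact zeros at cycle boundaries (guard against fp wobble)
    atBoundary <- active & abs(uAll - round(uAll)) < 1e-9 & l@phaseOffset == 0
    w[atBoundary] <- 0
    S[, j] <- (l@strainAmplitude / 100) * w
  }
  trans <- matrix(0, nFrames, 2)
  if (any(motion@translationMm != 0)) {
    ph <- 2 * pi * pmax(uAll, 0)
    trans[, 1] <- motion@translationMm[1] * sin(ph) * (k >= motion@restFrames)
    trans[, 2] <- motion@translationMm[2] * sin(ph) * (k >= motion@restFrames)
  }
  list(times = times, strain = S, translation = trans, nFrames = nFrames)
}

# Piecewise-linear through-depth strain profile: constant within each layer,
# linear blends across inter-layer gaps and over an edge margin to zero
# outside the muscle stack.
strainAtDepth <- function(depthMm, layerStrainRow, layers, edgeMm = 1.0) {
  rng <- t(vapply(layers, function(l) l@depthRange, numeric(2)))
  xs <- c(rng[1, 1] - edgeMm)
  ys <- c(0)
  for (j in seq_along(layers)) {
    xs <- c(xs, rng[j, 1], rng[j, 2])
    ys <- c(ys, layerStrainRow[j], layerStrainRow[j])
  }
  xs <- c(xs, rng[nrow(rng), 2] + edgeMm)
  ys <- c(ys, 0)
  approx(xs, ys, xout = depthMm, rule = 2)$y
}

# Scatterer field in mm coordinates over the image extent plus a lateral
# margin (so stretching never pulls blank space into view).
makeScatterers <- function(scene, marginMm = 4) {
  extentMm <- scene@imageSize * scene@pixelSpacingMm   # (depth, lateral)
  n <- round(scene@speckleDensity *
             (extentMm[1] + 2) * (extentMm[2] + 2 * marginMm))
  withSeed(scene@seed, {
    data.frame(
      depth = runif(n, -1, extentMm[1] + 1),
      lateral = runif(n, -marginMm, extentMm[2] + marginMm),
      amplitude = abs(rnorm(n, 1, 0.35)))
  })
}

# Render one frame from advected scatterers; returns unnormalized intensity.
renderFromScatterers <- function(scene, depth, lateral, amplitude) {
  cppRenderFrame(scene@imageSize[1], scene@imageSize[2],
                 depth / scene@pixelSpacingMm[1],
                 lateral / scene@pixelSpacingMm[2],
                 amplitude,
                 scene@pointSpreadMm[1] / scene@pixelSpacingMm[1],
                 scene@pointSpreadMm[2] / scene@pixelSpacingMm[2])
}

quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255

#' Generate a single synthetic speckle frame
#'
#' Draws a reproducible uniform scatterer field at the configured density,
#' convolves it with the Gaussian point spread and normalizes to `[0, 1]`
#' (8-bit quantized). With `speckleDensity = 0` the frame is a uniform
#' background (plus sensor noise if configured).
#'
#' @param scene a [SceneConfig-class].
#' @return numeric matrix (rows x cols) with attribute `"scatterers"`, the
#'   scatterer site table used.
#' @export
makeSpeckleFrame <- function(scene) {
  stopifnot(is(scene, "SceneConfig"))
  validObject(scene)
  sc <- makeScatterers(scene)
  img <- renderFromScatterers(scene, sc$depth, sc$lateral, sc$amplitude)
  norm <- max(stats::quantile(img, 0.995), 1e-12)
  img <- img / norm * 0.9
  if (scene@noiseSd > 0)
    img <- img + withSeed(subSeed(scene@seed, 1L),
                          matrix(rnorm(length(img), 0, scene@noiseSd),
                                 nrow(img)))
  img <- quantize8(img)
  attr(img, "scatterers") <- sc
  img
}

#' Render a full synthetic speckle video with exact ground truth
#'
#' Every frame is rendered directly from the analytically advected scatterer
#' field: within each muscle layer the lateral (along-fiber) coordinate is
#' stretched by `1 + s_l(t)` about the image's lateral center, with linear
#' through-depth blending at layer boundaries; optional rigid translation is
#' added on top. The integrated stretch over any segment inside a layer
#' therefore equals the layer's ground-truth deformation exactly. The sync
#' channel emits three contact-switch events per cycle: start (midline),
#' 20-degree reach (mid-cycle) and stop (back at midline).
#'
#' @param scene a [SceneConfig-class].
#' @param layers list of [LayerSpec-class]; depth ranges must be disjoint,
#'   ordered top to bottom, and fit inside the image.
#' @param motion a [MotionModel-class].
#' @return list with elements `sequence` ([FrameSequence-class]) and
#'   `groundTruth` ([GroundTruth-class]).
#' @export
renderSequence <- function(scene, layers = defaultLayers(),
                           motion = MotionModel()) {
  stopifnot(is(scene, "SceneConfig"), is(motion, "MotionModel"))
  validObject(scene); validObject(motion)
  checkLayers(layers)
  extentMm <- scene@imageSize * scene@pixelSpacingMm
  maxDepth <- max(vapply(layers, function(l) l@depthRange[2], 0))
  if (maxDepth > extentMm[1])
    stop("layers do not fit inside the image depth", call. = FALSE)

  tl <- motionTimeline(layers, motion, scene@frameRateHz)
  sc <- makeScatterers(scene)
  centerLat <- extentMm[2] / 2
  edgeMm <- 1.0

  sProf0 <- strainAtDepth(sc$depth, rep(0, length(layers)), layers, edgeMm)
  stopifnot(all(sProf0 == 0))

  arr <- array(0, c(scene@imageSize[1], scene@imageSize[2], tl$nFrames))
  norm <- NULL
  noiseStatic <- if (scene@noiseSd > 0 && scene@noiseMode == "static")
    withSeed(subSeed(scene@seed, 1L),
             matrix(rnorm(prod(scene@imageSize), 0, scene@noiseSd),
                    scene@imageSize[1])) else NULL
  for (k in seq_len(tl$nFrames)) {
    s <- strainAtDepth(sc$depth, tl$strain[k, ], layers, edgeMm)
    lat <- centerLat + (1 + s) * (sc$lateral - centerLat) +
      tl$translation[k, 2]
    dep <- sc$depth + tl$translation[k, 1]
    img <- renderFromScatterers(scene, dep, lat, sc$amplitude)
    if (is.null(norm)) norm <- max(stats::quantile(img, 0.995), 1e-12)
    img <- img / norm * 0.9
    if (scene@noiseSd > 0) {
      img <- img + if (scene@noiseMode == "static") noiseStatic else
        withSeed(subSeed(scene@seed, 100L + k),
                 matrix(rnorm(length(img), 0, scene@noiseSd), nrow(img)))
    }
    arr[, , k] <- quantize8(img)
  }

  fpc <- motion@cyclePeriodS * scene@frameRateHz   # frames per cycle
  cyc <- seq_len(motion@nCycles)
  startF <- motion@restFrames + round((cyc - 1) * fpc) + 1L
  sync <- data.frame(
    frame = as.integer(c(startF, startF + round(fpc / 2), startF + round(fpc))),
    type = rep(c("start", "reach", "stop"), each = motion@nCycles),
    cycle = rep(cyc, 3L))
  sync <- sync[order(sync$frame, match(sync$type, c("stop", "start", "reach"))), ]
  sync$time_s <- (sync$frame - 1L) * (1 / scene@frameRateHz)
  rownames(sync) <- NULL

  seqn <- FrameSequence(arr, 1 / scene@frameRateHz, scene@pixelSpacingMm,
                        sync, metadata = list(seed = scene@seed,
                                              nCycles = motion@nCycles))
  curves <- 100 * tl$strain
  colnames(curves) <- vapply(layers, function(l) l@label, "")
  gt <- new("GroundTruth", curves = curves,
            layerStrain = tl$strain, translationMm = tl$translation,
            times = tl$times, layers = layers,
            centerLateralMm = centerLat, edgeMm = edgeMm)
  validObject(gt)
  list(sequence = seqn, groundTruth = gt)
}

#' Advect points by the exact ground-truth displacement field
#'
#' Applies the same analytic transform that moved the scatterers: lateral
#' stretch about the image center scaled by the through-depth strain profile,
#' plus the rigid translation. Frame index is 1-based.
#'
#' @param gt a [GroundTruth-class].
#' @param pointsMm matrix n x 2 of frame-1 (depth, lateral) coordinates in mm.
#' @param frame 1-based frame index.
#' @return matrix n x 2 of advected coordinates in mm.
#' @export
advectPoints <- function(gt, pointsMm, frame) {
  stopifnot(is(gt, "GroundTruth"))
  pointsMm <- rbind(pointsMm)
  s <- strainAtDepth(pointsMm[, 1], gt@layerStrain[frame, ], gt@layers,
                     gt@edgeMm)
  lat <- gt@centerLateralMm + (1 + s) * (pointsMm[, 2] - gt@centerLateralMm) +
    gt@translationMm[frame, 2]
  dep <- pointsMm[, 1] + gt@translationMm[frame, 1]
  cbind(depth = dep, lateral = lat)
}
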