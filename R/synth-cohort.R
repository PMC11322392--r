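#' @include synth-speckle.R
NULL

# Look up the mean amplitude for (group, direction, muscle) in the effect map.
effectLookup <- function(groupEffects, group, direction, muscle) {
  hit <- groupEffects$group == group & groupEffects$direction == direction &
    groupEffects$muscle == muscle
  if (!any(hit))
    stop(sprintf("no group effect defined for (%s, %s, %s)",
                 group, direction, muscle), call. = FALSE)
  groupEffects$amplitude[which(hit)[1L]]
}

# Draw one subject's five per-muscle amplitudes for one direction/timepoint:
# group mean + shared subject deviation + muscle-specific deviation. The two
# components partition betweenSubjectSd^2 via subjectCorrelation, giving a
# compound-symmetric between-subject covariance across muscles.
drawAmplitudes <- function(config, group, direction, timepoint, sharedDev) {
  mu <- vapply(MUSCLES, function(m)
    effectLookup(config@groupEffects, group, direction, m), 0)
  if (timepoint == "followup" && group == "WAD")
    mu <- mu + config@followupEffects[MUSCLES]
  sdIndep <- config@betweenSubjectSd * sqrt(1 - config@subjectCorrelation)
  mu + sharedDev + rnorm(5L, 0, sdIndep)
}

#' Simulate a whole cohort at the statistics level
#'
#' Draws every subject's per-muscle ground-truth amplitudes from the
#' configured effect structure and converts them directly into the
#' 25-variable feature table through the package's own deformation-curve and
#' area code (one cycle of the configured waveform sampled at `frameRateHz`),
#' bypassing rendering and tracking. This is the fast path used for
#' inference-level simulation studies; [simulateCohort()] is the full
#' imaging-level path.
#'
#' @param config a [CohortConfig-class].
#' @param directions character, rotation directions to simulate.
#' @param motion a [MotionModel-class]; its waveform defines the within-cycle
#'   deformation shape (default biphasic: elongation with a shortening
#'   undershoot, so both area lobes are populated).
#' @param frameRateHz sampling rate of the underlying curves.
#' @return a feature table (data.frame): metadata columns `subject`, `group`,
#'   `sex`, `age`, `wad_grade`, `timepoint`, `direction` followed by the 25
#'   feature columns (5 muscles x 5 statistics), with the drawn amplitudes
#'   attached as attribute `"amplitudes"`.
#' @export
simulateFeatureTable <- function(config = CohortConfig(),
                                 directions = c("right", "left"),
                                 motion = MotionModel(waveform = "biphasic"),
                                 frameRateHz = 50) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  withSeed(config@seed, {
    n <- config@nPerGroup
    subjects <- data.frame(
      subject = sprintf("S%03d", seq_len(2L * n)),
      group = rep(c("WAD", "control"), each = n),
      # 76% women in both groups, as in the study population
      sex = unlist(lapply(1:2, function(i)
        sample(rep(c("F", "M"), c(round(0.76 * n), n - round(0.76 * n)))))),
      age = round(rnorm(2L * n, 41.5, 10.6)),
      stringsAsFactors = FALSE)
    subjects$wad_grade <- ifelse(
      subjects$group == "WAD", sample(c("II", "III"), 2L * n, TRUE), "none")
    sdShared <- config@betweenSubjectSd * sqrt(config@subjectCorrelation)
    nRows <- nrow(subjects) * length(config@timepoints) * length(directions)
    feats <- matrix(NA_real_, nRows, 25L)
    sIdx <- integer(nRows); tpLab <- dirLab <- character(nRows)
    ampRec <- matrix(NA_real_, nRows, 5L, dimnames = list(NULL, MUSCLES))
    i <- 0L
    for (s in seq_len(nrow(subjects))) {
      sharedDev <- rnorm(1L, 0, sdShared)
      for (tp in config@timepoints) for (dir in directions) {
        a <- drawAmplitudes(config, subjects$group[s], dir, tp, sharedDev)
        i <- i + 1L
        feats[i, ] <- amplitudeFeatures(a, motion, frameRateHz)
        sIdx[i] <- s; tpLab[i] <- tp; dirLab[i] <- dir
        ampRec[i, ] <- a
      }
    }
    colnames(feats) <- names(amplitudeFeatures(rep(1, 5), motion, frameRateHz))
    tab <- cbind(subjects[sIdx, ], timepoint = tpLab, direction = dirLab,
                 as.data.frame(feats))
    rownames(tab) <- NULL
    attr(tab, "amplitudes") <- data.frame(
      subject = rep(subjects$subject[sIdx], each = 5L),
      timepoint = rep(tpLab, each = 5L), direction = rep(dirLab, each = 5L),
      muscle = rep(MUSCLES, nRows), amplitude = as.vector(t(ampRec)))
    tab
  })
}

# The 25-feature vector implied by a set of true per-muscle amplitudes:
# each muscle's exact one-cycle deformation curve pushed through the
# package's rate and area decomposition. The decomposition is positively
# homogeneous (areas and RMS scale linearly with the curve, above/below
# swap under sign flip), so the unit-amplitude decomposition is computed
# once per motion model and scaled -- identical values, none of the cost.
.unitFeatureCache <- new.env(parent = emptyenv())

unitAmplitudeStats <- function(motion, frameRateHz, sign = 1) {
  key <- paste(motion@waveform, motion@undershoot, motion@cyclePeriodS,
               frameRateHz, sign, sep = "|")
  hit <- .unitFeatureCache[[key]]
  if (!is.null(hit)) return(hit)
  dt <- 1 / frameRateHz
  nF <- round(motion@cyclePeriodS * frameRateHz)
  u <- (seq_len(nF) - 1L) / nF
  w <- sign * cycleWaveform(u, motion@waveform, motion@undershoot)
  curve <- new("DeformationCurve", times = (seq_len(nF) - 1L) * dt,
               values = w, referenceLengthMm = 15,
               valid = rep(TRUE, nF), muscle = "", direction = "")
  dec <- decomposeAreas(curve)
  out <- c(total = dec@total, above = dec@areaAbove, below = dec@areaBelow,
           diff = dec@difference, raterms = dec@rateRms)
  .unitFeatureCache[[key]] <- out
  out
}

amplitudeFeatures <- function(amplitudes, motion, frameRateHz) {
  pos <- unitAmplitudeStats(motion, frameRateHz, 1)
  neg <- unitAmplitudeStats(motion, frameRateHz, -1)
  out <- numeric(0)
  for (j in seq_along(MUSCLES)) {
    a <- amplitudes[j]
    f <- abs(a) * (if (a >= 0) pos else neg)
    out <- c(out, setNames(f, paste(MUSCLES[j], FEATURE_STATS, sep = "_")))
  }
  out
}

#' Simulate an imaging-level cohort of speckle videos
#'
#' For each subject and rotation direction, draws per-muscle amplitudes from
#' the configured effect structure (group mean + between-subject noise, with
#' WAD follow-up shifts when requested) and renders a full speckle video via
#' [renderSequence()], recording complete provenance: the per-subject seed
#' and the drawn amplitudes.
#'
#' @param config a [CohortConfig-class].
#' @param scene a [SceneConfig-class] (per-subject seeds are derived from
#'   `config@seed`; the scene's own seed is ignored).
#' @param motion a [MotionModel-class].
#' @param directions rotation directions to render.
#' @param timepoint which timepoint to render.
#' @return list of per-subject records, each with `meta` (one-row data.frame),
#'   and one entry per direction holding `sequence`, `groundTruth` and
#'   `amplitudes`.
#' @export
simulateCohort <- function(config = CohortConfig(nPerGroup = 2),
                           scene = SceneConfig(),
                           motion = MotionModel(),
                           directions = c("right", "left"),
                           timepoint = "baseline") {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  n <- config@nPerGroup
  groups <- rep(c("WAD", "control"), each = n)
  out <- vector("list", 2L * n)
  sdShared <- config@betweenSubjectSd * sqrt(config@subjectCorrelation)
  for (s in seq_len(2L * n)) {
    sseed <- subSeed(config@seed, s)
    rec <- withSeed(sseed, {
      sharedDev <- rnorm(1L, 0, sdShared)
      sex <- sample(c("F", "M"), 1L, prob = c(0.76, 0.24))
      age <- round(rnorm(1L, 41.5, 10.6))
      dirRes <- list()
      for (dir in directions) {
        a <- drawAmplitudes(config, groups[s], dir, timepoint, sharedDev)
        lay <- defaultLayers(amplitudes = setNames(a, MUSCLES))
        sc <- scene
        sc@seed <- subSeed(sseed, match(dir, c("right", "left")))
        dirRes[[dir]] <- c(renderSequence(sc, lay, motion),
                           list(amplitudes = setNames(a, MUSCLES),
                                seed = sc@seed))
      }
      meta <- data.frame(subject = sprintf("S%03d", s), group = groups[s],
                         sex = sex, age = age,
                         wad_grade = if (groups[s] == "WAD") "II" else "none",
                         timepoint = timepoint, seed = sseed,
                         stringsAsFactors = FALSE)
      c(list(meta = meta), dirRes)
    })
    out[[s]] <- rec
  }
  out
}
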