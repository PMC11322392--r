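# Shared fixtures: small phantoms and feature tables built in code.

# Small, fast imaging scene used across tracking tests (30 mm depth so the
# default five-layer stack fits).
testScene <- function(seed = 7L, ...) {
  SceneConfig(imageSize = c(200L, 160L), seed = seed, ...)
}

# Two-cycle motion so sequences stay short; analysis segment = cycle 2.
testMotion <- function(...) MotionModel(nCycles = 2, restFrames = 10, ...)

# Cache the standard rendered phantom: rendering is deterministic, so one
# instance serves many tests.
.phantomCache <- new.env(parent = emptyenv())
testPhantom <- function(seed = 7L, amplitudes = NULL, motion = testMotion()) {
  key <- paste(seed, paste(amplitudes, collapse = ","),
               motion@nCycles, motion@waveform,
               paste(motion@translationMm, collapse = ","), sep = "|")
  if (is.null(.phantomCache[[key]])) {
    layers <- if (is.null(amplitudes)) defaultLayers()
              else defaultLayers(amplitudes = amplitudes)
    .phantomCache[[key]] <- renderSequence(testScene(seed), layers, motion)
  }
  .phantomCache[[key]]
}

# Deterministic synthetic deformation curve object.
makeCurve <- function(values, dt = 0.02, valid = NULL) {
  n <- length(values)
  new("DeformationCurve", times = (seq_len(n) - 1L) * dt,
      values = as.numeric(values), referenceLengthMm = 15,
      valid = if (is.null(valid)) rep(TRUE, n) else valid,
      muscle = "", direction = "")
}

# Fine-grid numerical integration oracle for the area decomposition of a
# piecewise-linear curve: evaluate the interpolant on a dense grid (the
# uniform grid united with the breakpoints) and integrate the positive and
# negative parts cell by cell, splitting a cell at its sign change. This is
# a local per-cell computation, independent of the package's global
# crossing-insertion + signed-run path.
fineGridAreas <- function(times, values, nGrid = 1e5) {
  tg <- sort(unique(c(seq(times[1L], times[length(times)],
                          length.out = nGrid), times)))
  yg <- approx(times, values, xout = tg)$y
  dt <- diff(tg)
  y0 <- head(yg, -1L); y1 <- yg[-1L]
  above <- below <- 0
  same <- y0 * y1 >= 0
  pos <- same & (y0 + y1 > 0)
  neg <- same & (y0 + y1 < 0)
  above <- sum(dt[pos] * (y0[pos] + y1[pos]) / 2)
  below <- -sum(dt[neg] * (y0[neg] + y1[neg]) / 2)
  cross <- which(!same)
  for (i in cross) {
    th <- y0[i] / (y0[i] - y1[i])
    a0 <- dt[i] * th * y0[i] / 2          # triangle on the y0 side
    a1 <- dt[i] * (1 - th) * y1[i] / 2    # triangle on the y1 side
    if (y0[i] > 0) { above <- above + a0; below <- below - a1 }
    else           { below <- below - a0; above <- above + a1 }
  }
  list(above = above, below = below, total = above + below,
       difference = above - below)
}

# Random subject x muscle long table for ANOVA oracle tests: balanced
# split-plot design with optional planted effects.
makeAnovaTable <- function(nPerGroup = 6, groupDelta = 0, interDelta = 0,
                           sexBalanced = TRUE, seed = 1) {
  withr::with_seed(seed, {
    n <- 2L * nPerGroup
    subj <- sprintf("S%02d", seq_len(n))
    group <- rep(c("WAD", "control"), each = nPerGroup)
    # same F:M pattern inside each group keeps sex orthogonal to group,
    # so sequential sums of squares equal the unadjusted cell-means ones
    sex <- if (sexBalanced)
      rep(rep_len(c("F", "M"), nPerGroup), 2L) else
      sample(c("F", "M"), n, replace = TRUE)
    tab <- data.frame(subject = subj, group = group, sex = sex)
    base <- c(TR = 2, SP = 3, Scap = 4, Scerv = 5, MF = 6)
    for (m in MUSCLES) {
      mu <- base[[m]] + ifelse(group == "WAD", groupDelta, 0) +
        ifelse(group == "WAD" & m %in% c("Scerv", "MF"), interDelta, 0)
      for (st in FEATURE_STATS)
        tab[[paste(m, st, sep = "_")]] <- mu + rnorm(n)
    }
    tab
  })
}

# Brute-force split-plot sums of squares for a BALANCED design (equal group
# sizes; sex balanced within group when used). Classical cell-means
# formulas, independent of the package's aov-based path.
bruteForceSplitPlot <- function(long, withSex = FALSE) {
  y <- long$value
  subj <- factor(long$subject); musc <- factor(long$muscle)
  grp <- factor(long$group); sex <- factor(long$sex)
  k <- nlevels(musc); N <- nlevels(subj)
  gm <- mean(y)
  subjMean <- tapply(y, subj, mean)
  grpOfSubj <- tapply(as.character(grp), subj, `[`, 1L)
  sexOfSubj <- tapply(as.character(sex), subj, `[`, 1L)
  ssBetweenTot <- k * sum((subjMean - gm)^2)
  ssGroup <- k * sum(tapply(subjMean, grpOfSubj, length) *
                       (tapply(subjMean, grpOfSubj, mean) - gm)^2)
  ssSex <- if (withSex)
    k * sum(tapply(subjMean, sexOfSubj, length) *
              (tapply(subjMean, sexOfSubj, mean) - gm)^2) else 0
  ssBetweenErr <- ssBetweenTot - ssGroup - ssSex
  muscMean <- tapply(y, musc, mean)
  ssMusc <- N * sum((muscMean - gm)^2)
  cellMean <- tapply(y, list(grp, musc), mean)
  grpMean <- tapply(y, grp, mean)
  nPerGrp <- table(grpOfSubj)
  ssInter <- 0
  for (g in levels(grp)) for (m in levels(musc))
    ssInter <- ssInter + nPerGrp[[g]] *
      (cellMean[g, m] - grpMean[[g]] - muscMean[[m]] + gm)^2
  ssWithinTot <- sum((y - subjMean[as.character(subj)])^2)
  ssWithinErr <- ssWithinTot - ssMusc - ssInter
  dfB <- N - 2L - if (withSex) 1L else 0L
  dfW <- (N - 2L) * (k - 1L)
  list(
    group = list(ss = ssGroup, df1 = 1, df2 = dfB,
                 F = (ssGroup / 1) / (ssBetweenErr / dfB),
                 eta = ssGroup / (ssGroup + ssBetweenErr)),
    sex = list(ss = ssSex, df1 = 1, df2 = dfB,
               F = if (withSex) (ssSex / 1) / (ssBetweenErr / dfB) else NA,
               eta = ssSex / (ssSex + ssBetweenErr)),
    muscle = list(ss = ssMusc, df1 = k - 1, df2 = dfW,
                  F = (ssMusc / (k - 1)) / (ssWithinErr / dfW),
                  eta = ssMusc / (ssMusc + ssWithinErr)),
    interaction = list(ss = ssInter, df1 = k - 1, df2 = dfW,
                       F = (ssInter / (k - 1)) / (ssWithinErr / dfW),
                       eta = ssInter / (ssInter + ssWithinErr)))
}
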