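# ROI placement, point tracking and the linear strain fit.

test_that("ROI placement spaces measuring points evenly and checks borders", {
  r <- testPhantom()
  roi <- placeROI(r$sequence, "Scerv", c(19.3, 4.5), c(19.3, 19.5))
  expect_equal(roi@nominalLengthMm, 15.0)
  expect_identical(roi@nPoints, 15L)

  roi2 <- placeROI(r$sequence, "x", c(10, 5), c(10, 20), nPoints = 2)
  expect_equal(roi2@points[1L, ], c(depth = 10, lateral = 5))
  expect_equal(roi2@points[2L, ], c(depth = 10, lateral = 20))

  roi5 <- placeROI(r$sequence, "x", c(10, 5), c(10, 20), nPoints = 5)
  expect_equal(diff(roi5@points[, "lateral"]), rep(3.75, 4L))

  expect_error(placeROI(r$sequence, "x", c(0.1, 5), c(0.1, 20)), "border")
})

test_that("identical frames track to zero displacement", {
  r <- testPhantom()
  f <- frames(r$sequence)[, , 1L]
  pts <- cbind(rep(60, 5), seq(40, 120, length.out = 5))
  tr <- trackPair(f, f, pts)
  expect_true(all(tr$valid))
  expect_true(all(abs(tr$drow) < 1e-6 & abs(tr$dcol) < 1e-6))
})

test_that("a one-pixel axial shift is recovered within 0.1 px", {
  r <- testPhantom()
  f <- frames(r$sequence)[, , 1L]
  shifted <- rbind(f[1L, , drop = FALSE], f[-nrow(f), ])  # content moves +1 row
  pts <- cbind(seq(40, 160, length.out = 6), rep(80, 6))
  tr <- trackPair(f, shifted, pts)
  expect_true(all(tr$valid))
  expect_true(all(abs(tr$drow - 1) < 0.1))
  expect_true(all(abs(tr$dcol) < 0.1))
})

test_that("pure temporal-noise frames flag most points invalid", {
  scene <- SceneConfig(imageSize = c(128L, 128L), speckleDensity = 0,
                       noiseSd = 0.05, noiseMode = "temporal", seed = 13L)
  r <- renderSequence(scene, list(LayerSpec("TR", c(2, 7), 0)),
                      MotionModel(nCycles = 1, restFrames = 0))
  f1 <- frames(r$sequence)[, , 1L]
  f2 <- frames(r$sequence)[, , 2L]
  expect_false(identical(f1, f2))
  pts <- cbind(runif(20, 30, 90), runif(20, 30, 90))
  tr <- trackPair(f1, f2, pts)
  expect_gt(mean(!tr$valid), 0.5)
})

test_that("linear strain fit matches the closed-form regression oracle", {
  x <- seq(-7.5, 7.5, length.out = 15)
  # rigid motion: common displacement, zero strain
  f <- fitLinearStrain(x, rep(0.3, 15))
  expect_equal(f$translation, 0.3)
  expect_equal(f$strainIncrement, 0)
  # exact gradient
  f <- fitLinearStrain(x, 0.01 * (x - mean(x)))
  expect_equal(f$strainIncrement, 0.01)
  # noisy slope: agree with lm() to 1e-10
  withr::with_seed(42, {
    for (i in 1:20) {
      y <- 0.02 * x + rnorm(15, 0, 0.05)
      f <- fitLinearStrain(x, y)
      co <- coef(lm(y ~ I(x - mean(x))))
      expect_equal(f$strainIncrement, unname(co[2L]), tolerance = 1e-10)
      expect_equal(f$translation, unname(co[1L]), tolerance = 1e-10)
    }
  })
  expect_error(fitLinearStrain(c(1, 1), c(0, 0)), "degenerate")
})

test_that("static sequences give constant length; single frame is trivial", {
  r <- renderSequence(testScene(seed = 21L), defaultLayers(rep(0, 5)),
                      MotionModel(nCycles = 1, restFrames = 5))
  roi <- defaultROIs(r$sequence)$Scap
  tr <- trackSequence(r$sequence, roi)
  expect_true(all(abs(roiLength(tr) - 15) < 1e-9))
  expect_true(all(tr@strainIncrement == 0))

  one <- FrameSequence(frames(r$sequence)[, , 1L, drop = FALSE], 0.02,
                       pixelSpacing(r$sequence))
  tr1 <- trackSequence(one, roi)
  expect_length(roiLength(tr1), 1L)
  expect_equal(roiLength(tr1), 15)
})

test_that("length accumulation is the exact product of strain increments", {
  r <- testPhantom()
  tr <- trackSequence(r$sequence, defaultROIs(r$sequence)$MF)
  n <- length(roiLength(tr))
  expect_equal(prod(1 + tr@strainIncrement[-1L]),
               roiLength(tr)[n] / roiLength(tr)[1L], tolerance = 1e-12)
})

test_that("a 5% uniform stretch peaks near 15.75 mm", {
  r <- testPhantom(seed = 7L, amplitudes = c(TR = 5, SP = 4, Scap = 5.5,
                                             Scerv = 7, MF = 7.5))
  tr <- trackSequence(r$sequence, defaultROIs(r$sequence)$TR)
  expect_lt(abs(max(roiLength(tr)) - 15.75), 0.08)
})

test_that("recovered peak deformation tracks ground truth for all layers", {
  amps <- c(TR = 3.5, SP = 4, Scap = 5.5, Scerv = 7, MF = 7.5)
  r <- testPhantom(seed = 7L, amplitudes = amps)
  rois <- defaultROIs(r$sequence)
  seg <- segmentCycle(r$sequence, 2L)
  for (m in MUSCLES) {
    tr <- trackSequence(r$sequence, rois[[m]])
    cv <- toDeformation(tr, referenceFrame = seg$start, frames = seg$frames)
    err <- abs(max(curveValues(cv)) - amps[[m]])
    expect_lt(err, max(0.5, 0.1 * amps[[m]]))
  }
})

test_that("pure translation yields near-zero deformation (rigid-motion null)", {
  r <- testPhantom(seed = 7L, amplitudes = rep(0, 5),
                   motion = testMotion(translationMm = c(0.4, 0.7)))
  rois <- defaultROIs(r$sequence)
  for (m in c("TR", "Scerv")) {
    tr <- trackSequence(r$sequence, rois[[m]])
    dev <- 100 * abs(roiLength(tr) - 15) / 15
    expect_lt(max(dev), 0.2)
  }
})
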