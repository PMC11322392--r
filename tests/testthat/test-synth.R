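# Synthetic phantom and cohort generator.

test_that("speckle frame generation is deterministic and density-controlled", {
  scene <- testScene(seed = 3L)
  f1 <- makeSpeckleFrame(scene)
  f2 <- makeSpeckleFrame(scene)
  expect_identical(f1, f2)

  flat <- makeSpeckleFrame(SceneConfig(imageSize = c(64L, 64L),
                                       speckleDensity = 0, noiseSd = 0,
                                       seed = 3L))
  expect_equal(length(unique(as.vector(flat))), 1L)

  sc1 <- attr(makeSpeckleFrame(testScene(seed = 3L)), "scatterers")
  sc2 <- attr(makeSpeckleFrame(testScene(seed = 3L,
                                         speckleDensity = 50)), "scatterers")
  expect_gt(nrow(sc2), nrow(sc1))

  expect_error(SceneConfig(imageSize = c(0L, 64L)), "positive")
})

test_that("zero-amplitude sequences are static and ground truth is zero", {
  r <- renderSequence(testScene(seed = 11L), defaultLayers(rep(0, 5)),
                      MotionModel(nCycles = 1, restFrames = 3))
  f <- frames(r$sequence)
  for (k in seq_len(nFrames(r$sequence)))
    expect_identical(f[, , k], f[, , 1L])
  expect_true(all(trueCurves(r$groundTruth) == 0))
})

test_that("ground-truth amplitude, rest segment and sync events are exact", {
  motion <- MotionModel(nCycles = 2, restFrames = 10)
  r <- testPhantom(seed = 7L, amplitudes = c(TR = 5, SP = 4, Scap = 5.5,
                                             Scerv = 7, MF = 7.5),
                   motion = motion)
  gt <- trueCurves(r$groundTruth)
  # raised cosine peaks at exactly the amplitude, mid-cycle
  midFrame <- 10L + 50L + 1L        # rest + half of the 100-frame cycle
  expect_identical(unname(gt[midFrame, "TR"]), 5)
  expect_equal(max(gt[, "TR"]), 5)
  # rest frames carry exactly zero deformation and displacement
  expect_true(all(gt[seq_len(10L), ] == 0))
  expect_true(all(r$groundTruth@translationMm[seq_len(10L), ] == 0))
  # three contact-switch events per cycle
  ev <- syncEvents(r$sequence)
  expect_identical(nrow(ev), 6L)
  expect_identical(as.vector(table(ev$type)[c("start", "reach", "stop")]),
                   rep(2L, 3L))
})

test_that("ten cycles emit thirty sync events", {
  scene <- SceneConfig(imageSize = c(200L, 32L), speckleDensity = 2,
                       seed = 1L)
  r <- renderSequence(scene, defaultLayers(), MotionModel())
  expect_identical(nrow(syncEvents(r$sequence)), 30L)
})

test_that("advecting ground-truth points reproduces the layer curves exactly", {
  r <- testPhantom(seed = 7L)
  gt <- r$groundTruth
  for (j in seq_along(gt@layers)) {
    l <- gt@layers[[j]]
    d <- mean(l@depthRange)
    p0 <- rbind(c(d, 6), c(d, 18))        # 12 mm apart, inside the layer
    L0 <- 12
    for (k in c(1L, 30L, 61L, 90L, 111L)) {
      pk <- advectPoints(gt, p0, k)
      Lk <- sqrt(sum((pk[2L, ] - pk[1L, ])^2))
      expect_lt(abs(100 * (Lk - L0) / L0 - trueCurves(gt)[k, j]), 1e-6)
    }
  }
})

test_that("identical configuration and seed give byte-identical output", {
  a <- renderSequence(testScene(seed = 5L), defaultLayers(),
                      MotionModel(nCycles = 1, restFrames = 2))
  b <- renderSequence(testScene(seed = 5L), defaultLayers(),
                      MotionModel(nCycles = 1, restFrames = 2))
  expect_identical(frames(a$sequence), frames(b$sequence))
  expect_identical(trueCurves(a$groundTruth), trueCurves(b$groundTruth))
})

test_that("overlapping layers are rejected", {
  bad <- list(LayerSpec("TR", c(2, 8)), LayerSpec("SP", c(6, 12)))
  expect_error(renderSequence(testScene(), bad, testMotion()), "disjoint")
})

test_that("statistics-level cohort has the configured size and structure", {
  cfg <- CohortConfig(nPerGroup = 34, seed = 9L)
  tab <- simulateFeatureTable(cfg, directions = "right")
  expect_identical(nrow(tab), 68L)
  expect_identical(sum(tab$group == "WAD"), 34L)
  expect_true(all(featureColumns() %in% names(tab)))
  expect_identical(length(featureColumns()), 25L)
  # reproducible
  tab2 <- simulateFeatureTable(cfg, directions = "right")
  expect_identical(tab, tab2)
})

test_that("zero between-subject SD gives identical same-group ground truth", {
  cfg <- CohortConfig(nPerGroup = 3, betweenSubjectSd = 0, seed = 2L)
  tab <- simulateFeatureTable(cfg, directions = "right")
  w <- tab[tab$group == "WAD", featureColumns()]
  expect_true(all(apply(w, 2L, function(x) diff(range(x)) == 0)))
})

test_that("planted deep-muscle deficit shows in the generator's own draws", {
  cfg <- CohortConfig(nPerGroup = 150, seed = 4L)
  tab <- simulateFeatureTable(cfg, directions = "right")
  amps <- attr(tab, "amplitudes")
  deep <- amps[amps$muscle %in% c("Scap", "Scerv", "MF") &
                 amps$direction == "right", ]
  grp <- merge(deep, tab[, c("subject", "group")][!duplicated(tab$subject), ])
  mWad <- mean(grp$amplitude[grp$group == "WAD"])
  mCtl <- mean(grp$amplitude[grp$group == "control"])
  expect_lt(mWad, mCtl)
  expect_equal(mCtl - mWad, 2.0, tolerance = 0.15)
})

test_that("imaging-level cohort records provenance and honours group effects", {
  cfg <- CohortConfig(nPerGroup = 2, seed = 12L)
  scene <- SceneConfig(imageSize = c(200L, 64L), speckleDensity = 4)
  cohort <- simulateCohort(cfg, scene, MotionModel(nCycles = 1, restFrames = 2),
                           directions = "right")
  expect_length(cohort, 4L)
  for (rec in cohort) {
    expect_true(all(c("meta", "right") %in% names(rec)))
    expect_true(is(rec$right$sequence, "FrameSequence"))
    expect_true(is(rec$right$groundTruth, "GroundTruth"))
    expect_length(rec$right$amplitudes, 5L)
    expect_true(is.numeric(rec$meta$seed))
  }
})
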