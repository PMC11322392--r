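# Mixed-design and within-subject repeated-measures ANOVA machinery.

test_that("mixed ANOVA matches the brute-force cell-means oracle", {
  withr::with_seed(101, {
    for (i in 1:25) {
      tab <- makeAnovaTable(nPerGroup = sample(4:8, 1L),
                            groupDelta = runif(1, -1, 1),
                            interDelta = runif(1, -1, 1), seed = i)
      for (withSex in c(FALSE, TRUE)) {
        res <- mixedAnova(tab, dv = "total", adjustSex = withSex)
        long <- SpeckleStrain:::gatherStat(tab, "total")
        bf <- bruteForceSplitPlot(long, withSex = withSex)
        pick <- function(e) res[res$effect == e, ]
        # GG may rescale within dfs; compare uncorrected F/SS/eta and dfs
        expect_equal(pick("group")$F, bf$group$F, tolerance = 1e-8)
        expect_equal(pick("group")$ss, bf$group$ss, tolerance = 1e-8)
        expect_equal(pick("group")$eta_p2, bf$group$eta, tolerance = 1e-8)
        expect_equal(pick("group")$df2, bf$group$df2)
        expect_equal(pick("muscle")$F, bf$muscle$F, tolerance = 1e-8)
        expect_equal(pick("muscle")$eta_p2, bf$muscle$eta, tolerance = 1e-8)
        expect_equal(pick("group:muscle")$F, bf$interaction$F,
                     tolerance = 1e-8)
        expect_equal(pick("group:muscle")$ss, bf$interaction$ss,
                     tolerance = 1e-8)
        if (withSex)
          expect_equal(pick("sex")$F, bf$sex$F, tolerance = 1e-8)
      }
    }
  })
})

test_that("constant responses give all-zero F and effect sizes", {
  tab <- makeAnovaTable(nPerGroup = 4, seed = 1)
  for (col in featureColumns()) tab[[col]] <- 7
  res <- mixedAnova(tab, dv = "total")
  expect_true(all(res$F == 0))
  expect_true(all(res$eta_p2 == 0))
  expect_true(all(res$p == 1))
})

test_that("unbalanced designs are rejected explicitly", {
  tab <- makeAnovaTable(nPerGroup = 4, seed = 2)
  expect_error(mixedAnova(rbind(tab, tab[1L, ]), dv = "total"), "unbalanced")
})

test_that("Mauchly test agrees with stats::mauchly.test", {
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- 20L; k <- 4L
      wide <- matrix(rnorm(n * k), n) %*% matrix(runif(k * k, -1, 1), k)
      fit <- lm(wide ~ 1)
      ref <- stats::mauchly.test(fit, X = ~1)
      ours <- mauchlyTest(wide)
      expect_equal(ours$W, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
    }
  })
  # two within levels: sphericity trivially holds
  expect_identical(mauchlyTest(matrix(rnorm(20), 10))$W, 1)
})

test_that("Mauchly rejects at the nominal rate under sphericity and has power", {
  withr::with_seed(11, {
    rejNull <- mean(vapply(1:300, function(i) {
      wide <- matrix(rnorm(30 * 5), 30)           # spherical by construction
      mauchlyTest(wide)$p < 0.05
    }, TRUE))
    expect_gt(rejNull, 0.02)
    expect_lt(rejNull, 0.09)
    rejHet <- mean(vapply(1:100, function(i) {
      wide <- matrix(rnorm(30 * 5), 30) %*% diag(c(4, 2, 1, 0.5, 0.25))
      mauchlyTest(wide)$p < 0.05
    }, TRUE))
    expect_gt(rejHet, 0.8)
  })
})

test_that("Greenhouse-Geisser epsilon is bounded and exact when spherical", {
  withr::with_seed(19, {
    k <- 5L
    for (i in 1:20) {
      wide <- matrix(rnorm(15 * k), 15) %*% matrix(runif(k * k, -1, 1), k)
      eps <- ggEpsilon(wide)
      expect_gte(eps, 1 / (k - 1) - 1e-12)
      expect_lte(eps, 1 + 1e-12)
    }
    # construct data whose sample contrast covariance is exactly spherical
    C <- SpeckleStrain:::orthonormalContrasts(k)
    U <- qr.Q(qr(scale(matrix(rnorm(12 * (k - 1)), 12), scale = FALSE)))
    wide <- U %*% t(C) + matrix(rnorm(12), 12, k)   # + subject offsets
    expect_equal(ggEpsilon(wide), 1, tolerance = 1e-9)
    # hand-computed from the contrast covariance (direct matrix formula)
    wide2 <- matrix(rnorm(15 * k), 15) %*% matrix(runif(k * k, -1, 1), k)
    A <- t(C) %*% (cov(wide2) * 14) %*% C
    expect_equal(ggEpsilon(wide2),
                 sum(diag(A))^2 / ((k - 1) * sum(A * t(A))),
                 tolerance = 1e-12)
  })
})

test_that("GG correction is applied only when sphericity fails", {
  withr::with_seed(23, {
    tab <- makeAnovaTable(nPerGroup = 10, seed = 5)
    # strongly heterogeneous muscle variances violate sphericity
    for (j in seq_along(MUSCLES))
      tab[[paste0(MUSCLES[j], "_total")]] <-
        tab[[paste0(MUSCLES[j], "_total")]] * c(8, 4, 1, 0.3, 0.1)[j]
    res <- mixedAnova(tab, dv = "total")
    within <- res[res$effect %in% c("muscle", "group:muscle"), ]
    expect_true(all(within$mauchly_p < 0.05))
    expect_true(all(within$corrected))
    expect_true(all(within$epsilon_gg >= 0.25 & within$epsilon_gg < 1))
    expect_false(any(res$corrected[res$effect %in% c("group", "sex")]))
  })
})

test_that("post-hoc level contrasts honour the Bonferroni family of three", {
  tab <- makeAnovaTable(nPerGroup = 8, interDelta = -2, seed = 9)
  ph <- posthocLevelContrasts(tab, dv = "total")
  expect_identical(nrow(ph), 3L)
  expect_true(all(ph$p_bonferroni >= ph$p))
  expect_equal(ph$p_bonferroni, pmin(1, 3 * ph$p))
  # planted deep deficit: superficial-vs-deep is the strongest contrast on
  # average across replicates
  meanP <- rowMeans(vapply(1:20, function(i) {
    posthocLevelContrasts(makeAnovaTable(nPerGroup = 8, interDelta = -2,
                                         seed = 100 + i), dv = "total")$p
  }, numeric(3)))
  expect_identical(which.min(meanP), 2L)   # superficial vs deep
  expect_lt(meanP[2L], 0.05)
})

test_that("within-subject ANOVA matches its brute-force oracle", {
  bruteWithin <- function(long) {
    y <- long$value
    s <- factor(long$subject); tp <- factor(long$timepoint)
    m <- factor(long$muscle)
    N <- nlevels(s); kt <- nlevels(tp); km <- nlevels(m)
    gm <- mean(y)
    ssTp <- N * km * sum((tapply(y, tp, mean) - gm)^2)
    ssM <- N * kt * sum((tapply(y, m, mean) - gm)^2)
    cellTM <- tapply(y, list(tp, m), mean)
    ssTM <- N * sum((sweep(sweep(cellTM, 1, tapply(y, tp, mean)), 2,
                           tapply(y, m, mean)) + gm)^2)
    ms <- tapply(y, s, mean)
    ssSubj <- kt * km * sum((ms - gm)^2)
    cellST <- tapply(y, list(s, tp), mean)
    ssST <- km * sum((sweep(sweep(cellST, 1, ms), 2, tapply(y, tp, mean)) +
                        gm)^2) - 0
    cellSM <- tapply(y, list(s, m), mean)
    ssSM <- kt * sum((sweep(sweep(cellSM, 1, ms), 2, tapply(y, m, mean)) +
                        gm)^2)
    ssTot <- sum((y - gm)^2)
    ssRes <- ssTot - ssTp - ssM - ssTM - ssSubj - ssST - ssSM
    list(
      timepoint = (ssTp / (kt - 1)) / (ssST / ((N - 1) * (kt - 1))),
      muscle = (ssM / (km - 1)) / (ssSM / ((N - 1) * (km - 1))),
      inter = (ssTM / ((kt - 1) * (km - 1))) /
        (ssRes / ((N - 1) * (kt - 1) * (km - 1))))
  }
  withr::with_seed(33, {
    for (i in 1:10) {
      base <- makeAnovaTable(nPerGroup = 5, seed = 40 + i)
      t1 <- cbind(base, timepoint = "baseline")
      t2 <- cbind(base, timepoint = "followup")
      for (col in featureColumns()) t2[[col]] <- t2[[col]] + rnorm(10, 0.5)
      tab <- rbind(t1, t2)
      res <- withinSubjectAnova(tab, dv = "total")
      long <- SpeckleStrain:::gatherStat(tab, "total", extra = "timepoint")
      bf <- bruteWithin(long)
      expect_equal(res$F[res$effect == "timepoint"], bf$timepoint,
                   tolerance = 1e-8)
      expect_equal(res$F[res$effect == "muscle"], bf$muscle,
                   tolerance = 1e-8)
      expect_equal(res$F[res$effect == "timepoint:muscle"], bf$inter,
                   tolerance = 1e-8)
    }
  })
})

test_that("identical timepoints give a zero timepoint effect", {
  base <- makeAnovaTable(nPerGroup = 5, seed = 3)
  tab <- rbind(cbind(base, timepoint = "baseline"),
               cbind(base, timepoint = "followup"))
  res <- withinSubjectAnova(tab, dv = "total")
  expect_equal(res$F[res$effect == "timepoint"], 0)
})

test_that("unpaired subjects are dropped with a message", {
  base <- makeAnovaTable(nPerGroup = 5, seed = 4)
  tab <- rbind(cbind(base, timepoint = "baseline"),
               cbind(base[-1L, ], timepoint = "followup"))
  expect_message(res <- withinSubjectAnova(tab, dv = "total"), "unpaired")
  expect_true(is.data.frame(res))
})
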