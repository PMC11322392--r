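# PCA, OPLS-DA and the jackknife cross-validation.

test_that("preprocessing centers, scales, drops constants and inverts", {
  withr::with_seed(51, {
    X <- matrix(rnorm(60), 12, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    Z <- scale(X)
    attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
    pp <- preprocessMatrix(X)
    expect_equal(unname(pp$x), unname(as.matrix(Z)), tolerance = 1e-12)
    # already standardized input is unchanged
    pp2 <- preprocessMatrix(pp$x)
    expect_equal(pp2$x, pp$x, tolerance = 1e-12)
    # round trip
    expect_equal(inversePreprocess(pp), unname(X) * 1, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # constant column dropped with a message
    X2 <- cbind(X, const = 5)
    expect_message(pp3 <- preprocessMatrix(X2), "zero-variance")
    expect_identical(pp3$dropped, "const")
    expect_identical(ncol(pp3$x), 5L)
  })
})

test_that("PCA recovers structure with orthonormal, sign-fixed loadings", {
  withr::with_seed(52, {
    # rank-1 matrix: first component carries ~all variance
    u <- rnorm(30); v <- rnorm(6)
    X <- outer(u, v) + matrix(rnorm(180, 0, 1e-4), 30)
    m <- fitPCA(X, scale = FALSE)
    expect_gt(m$explainedVariance[1L], 0.999)
    # loadings orthonormal; reconstruction reproduces preprocessed X
    X2 <- matrix(rnorm(11 * 4), 11)
    m2 <- fitPCA(X2)
    expect_equal(crossprod(m2$loadings), diag(4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(m2$scores %*% t(m2$loadings), unname(m2$preprocess$x),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(diff(m2$explainedVariance) <= 1e-12))
    # deterministic sign: largest-magnitude loading element positive
    for (j in seq_len(ncol(m2$loadings))) {
      v <- m2$loadings[, j]
      expect_gt(v[which.max(abs(v))], 0)
    }
    # isotropic noise: roughly equal variance fractions
    m3 <- fitPCA(matrix(rnorm(500 * 5), 500))
    expect_lt(max(m3$explainedVariance) / min(m3$explainedVariance), 1.6)
    expect_error(fitPCA(matrix(1, 1, 3)), "2 rows")
  })
})

test_that("OPLS-DA concentrates loading on the discriminating variable", {
  withr::with_seed(53, {
    n <- 40L
    cl <- rep(c("A", "B"), each = n / 2)
    X <- matrix(rnorm(n * 8, 0, 0.2), n)
    X[cl == "B", 3L] <- X[cl == "B", 3L] + 4
    colnames(X) <- paste0("v", 1:8)
    m <- fitOplsDa(X, cl, nOrthogonal = 1L)
    expect_gt(abs(m$loadings[3L]), 2 * max(abs(m$loadings[-3L])))
    # predictive scores orthogonal to every orthogonal score vector
    expect_lt(abs(sum(m$scores * m$orthoScores[, 1L])), 1e-8)
    expect_error(fitOplsDa(X, rep("A", n)), "2 classes")
  })
})

test_that("with no orthogonal components OPLS-DA equals 1-component PLS", {
  withr::with_seed(54, {
    n <- 24L
    cl <- rep(c("A", "B"), each = n / 2)
    X <- matrix(rnorm(n * 6), n)
    colnames(X) <- paste0("v", 1:6)
    m <- fitOplsDa(X, cl, nOrthogonal = 0L)
    y <- as.numeric(cl == "B")
    pls <- mixOmics::pls(scale(X), y - mean(y), ncomp = 1, scale = FALSE,
                         mode = "regression")
    w <- pls$loadings$X[, 1L]
    # weight vectors match up to sign
    s <- sign(sum(w * m$weights))
    expect_equal(unname(s * w), unname(m$weights), tolerance = 1e-6)
  })
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  withr::with_seed(55, {
    acc <- vapply(1:15, function(i) {
      n <- 42L
      X <- matrix(rnorm(n * 10), n)
      colnames(X) <- paste0("v", 1:10)
      cl <- sample(rep(c("A", "B"), each = n / 2))
      crossvalidateJackknife(X, cl, seed = i)$accuracy
    }, 0)
    expect_gt(mean(acc), 0.3)
    expect_lt(mean(acc), 0.7)
  })
})

test_that("fold assignment is stratified, exhaustive and near-balanced", {
  cl <- rep(c("A", "B"), each = 34)
  folds <- SpeckleStrain:::makeFolds(cl, 7L, seed = 3L)
  expect_length(folds, 68L)
  sizes <- table(folds)
  expect_true(all(sizes >= 9L & sizes <= 10L))
  expect_identical(sum(sizes), 68L)           # every subject exactly once
  perClass <- table(folds, cl)
  expect_true(all(perClass >= 4L & perClass <= 6L))
  expect_identical(folds, SpeckleStrain:::makeFolds(cl, 7L, seed = 3L))
})

test_that("jackknife CIs flag planted signals and spare noise variables", {
  withr::with_seed(56, {
    hits <- 0L
    for (i in 1:10) {
      n <- 42L
      cl <- rep(c("A", "B"), each = n / 2)
      X <- matrix(rnorm(n * 10, 0, 0.1), n)
      X[cl == "B", 2L] <- X[cl == "B", 2L] + 5       # near-zero-noise signal
      colnames(X) <- paste0("v", 1:10)
      cv <- crossvalidateJackknife(X, cl, seed = i)
      if (cv$loadingTable$significant[2L]) hits <- hits + 1L
    }
    expect_identical(hits, 10L)

    noiseIncl <- vapply(1:10, function(i) {
      n <- 42L
      cl <- rep(c("A", "B"), each = n / 2)
      X <- matrix(rnorm(n * 10), n)
      X[cl == "B", 1L] <- X[cl == "B", 1L] + 3       # one real signal
      colnames(X) <- paste0("v", 1:10)
      cv <- crossvalidateJackknife(X, cl, seed = 100 + i)
      mean(!cv$loadingTable$significant[-1L])        # noise vars spared
    }, 0)
    expect_gte(mean(noiseIncl), 0.9)
  })
})

test_that("cross-validation is deterministic for a fixed seed", {
  withr::with_seed(57, {
    n <- 28L
    cl <- rep(c("A", "B"), each = n / 2)
    X <- matrix(rnorm(n * 6), n)
    colnames(X) <- paste0("v", 1:6)
  })
  a <- crossvalidateJackknife(X, cl, seed = 11L)
  b <- crossvalidateJackknife(X, cl, seed = 11L)
  expect_identical(a$folds, b$folds)
  expect_identical(a$loadingTable, b$loadingTable)
})
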