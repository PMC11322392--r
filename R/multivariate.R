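#' @include areas.R
NULL

#' Column-wise centering and unit-variance scaling
#'
#' SIMCA-style preprocessing: mean-center each column and scale to unit
#' variance. Zero-variance columns are excluded (with a message) and their
#' names recorded. The stored parameters invert the transform exactly.
#'
#' @param x numeric matrix (no missing values).
#' @param scale scale to unit variance (default `TRUE`); centering always on.
#' @return list of class `PreprocessedMatrix`: `x` (transformed), `center`,
#'   `scale`, `dropped` (names of excluded columns).
#' @export
preprocessMatrix <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values not allowed", call. = FALSE)
  ctr <- colMeans(x)
  sds <- apply(x, 2L, sd)
  dropped <- colnames(x)[sds == 0]
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  dropped <- colnames(x)[sds == 0]
  if (length(dropped))
    message("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
  keep <- sds > 0
  xt <- sweep(x[, keep, drop = FALSE], 2L, ctr[keep])
  scl <- if (scale) sds[keep] else rep(1, sum(keep))
  xt <- sweep(xt, 2L, scl, "/")
  structure(list(x = xt, center = ctr[keep], scale = scl, dropped = dropped),
            class = "PreprocessedMatrix")
}

#' Invert [preprocessMatrix()]
#' @param pp a `PreprocessedMatrix`.
#' @param x matrix on the preprocessed scale (default the stored one).
#' @return matrix on the original scale (dropped columns are absent).
#' @export
inversePreprocess <- function(pp, x = pp$x) {
  sweep(sweep(x, 2L, pp$scale, "*"), 2L, pp$center, "+")
}

#' Principal component analysis with a deterministic sign convention
#'
#' PCA of the centered/scaled matrix by singular-value decomposition
#' (`stats::prcomp`). Each loading vector is flipped so its
#' largest-magnitude element is positive, making results reproducible
#' across platforms.
#'
#' @param x numeric matrix (rows = observations).
#' @param nComponents number of components (default
#'   `min(nrow - 1, ncol)`).
#' @param scale unit-variance scaling flag, passed to [preprocessMatrix()].
#' @return list of class `PcaModel`: `scores`, `loadings`,
#'   `explainedVariance` (fractions), `sdev`, `preprocess`.
#' @export
fitPCA <- function(x, nComponents = NULL, scale = TRUE) {
  if (nrow(as.matrix(x)) < 2L) stop("need at least 2 rows", call. = FALSE)
  pp <- preprocessMatrix(x, scale = scale)
  maxC <- min(nrow(pp$x) - 1L, ncol(pp$x))
  if (is.null(nComponents)) nComponents <- maxC
  if (nComponents > maxC)
    stop("nComponents exceeds min(rows - 1, cols)", call. = FALSE)
  pc <- prcomp(pp$x, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2L, flip, "*")
  sco <- sweep(pc$x, 2L, flip, "*")
  totVar <- sum(pp$x^2) / (nrow(pp$x) - 1L)
  idx <- seq_len(nComponents)
  structure(list(scores = sco[, idx, drop = FALSE],
                 loadings = rot[, idx, drop = FALSE],
                 explainedVariance = pc$sdev[idx]^2 / totVar,
                 sdev = pc$sdev[idx], preprocess = pp),
            class = "PcaModel")
}

#' @export
print.PcaModel <- function(x, ...) {
  cat(sprintf("PcaModel: %d components over %d variables\n",
              ncol(x$scores), nrow(x$loadings)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explainedVariance), collapse = ", "),
      "\n")
  invisible(x)
}

# Core OPLS fit on an already preprocessed matrix and centered response.
# Returns weights/loadings of the single predictive component and the
# orthogonal component set. Trygg-Wold style: repeatedly split off the
# variation orthogonal to y, then fit one predictive PLS component.
oplsCore <- function(X, yc, nOrthogonal) {
  Wo <- Po <- NULL
  To <- NULL
  Xd <- X
  for (i in seq_len(nOrthogonal)) {
    w <- drop(crossprod(Xd, yc))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w
    no <- sqrt(sum(wo^2))
    if (no < 1e-12) break                 # no orthogonal variation left
    wo <- wo / no
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  w <- drop(crossprod(Xd, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t)) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  list(weights = w, scores = t, loadings = p, q = q,
       orthoWeights = Wo, orthoScores = To, orthoLoadings = Po)
}

#' Fit an OPLS-DA model for two classes
#'
#' Orthogonal projections to latent structures discriminant analysis: the
#' class membership is coded as a centered 0/1 response, `nOrthogonal`
#' components uncorrelated with it are split off, and a single predictive
#' component is fit on the filtered matrix. Per-variable predictive
#' loadings are the quantity later assessed by jackknifing. With
#' `nOrthogonal = 0` the model reduces to a 1-component PLS-DA.
#'
#' @param x numeric matrix, observations x variables.
#' @param classes factor-like with exactly two classes, >= 3 members each.
#' @param nOrthogonal number of orthogonal components (default 1).
#' @param scale unit-variance scaling flag.
#' @return list of class `OplsDaModel`: `weights`, `scores`, `loadings`,
#'   `q`, `orthoScores`, `orthoLoadings`, `orthoWeights`, `classes`
#'   (levels), `threshold`, `preprocess`.
#' @export
fitOplsDa <- function(x, classes, nOrthogonal = 1L, scale = TRUE) {
  cl <- factor(classes)
  if (nlevels(cl) != 2L)
    stop("need exactly 2 classes", call. = FALSE)
  if (min(table(cl)) < 3L)
    stop("each class needs >= 3 members", call. = FALSE)
  pp <- preprocessMatrix(x, scale = scale)
  y <- as.numeric(cl == levels(cl)[2L])
  yc <- y - mean(y)
  fit <- oplsCore(pp$x, yc, nOrthogonal)
  structure(c(fit, list(classes = levels(cl), yMean = mean(y),
                        preprocess = pp)),
            class = "OplsDaModel")
}

#' @export
print.OplsDaModel <- function(x, ...) {
  cat(sprintf(
    "OplsDaModel: %s vs %s; 1 predictive + %d orthogonal component(s)\n",
    x$classes[1L], x$classes[2L],
    if (is.null(x$orthoScores)) 0L else ncol(x$orthoScores)))
  invisible(x)
}

#' Predict classes with an OPLS-DA model
#'
#' New observations are preprocessed with the training parameters, deflated
#' by the orthogonal components, projected on the predictive component and
#' thresholded at the class midpoint.
#'
#' @param model an `OplsDaModel`.
#' @param newx matrix on the original variable scale (same columns as
#'   training).
#' @return list with `score` (predictive scores), `yhat` (continuous) and
#'   `class` (predicted labels).
#' @export
predictOplsDa <- function(model, newx) {
  pp <- model$preprocess
  newx <- as.matrix(newx)
  keep <- setdiff(colnames(newx), pp$dropped)
  if (!is.null(colnames(newx)) && length(keep) == length(pp$center))
    newx <- newx[, names(pp$center), drop = FALSE]
  Xn <- sweep(sweep(newx, 2L, pp$center), 2L, pp$scale, "/")
  if (!is.null(model$orthoWeights))
    for (i in seq_len(ncol(model$orthoWeights))) {
      to <- drop(Xn %*% model$orthoWeights[, i])
      Xn <- Xn - tcrossprod(to, model$orthoLoadings[, i])
    }
  t <- drop(Xn %*% model$weights)
  yhat <- model$yMean + t * model$q
  list(score = t, yhat = yhat,
       class = ifelse(yhat >= 0.5, model$classes[2L], model$classes[1L]))
}

# Stratified leave-out-p fold assignment: classes shuffled independently,
# then dealt consecutively over folds so sizes differ by at most one within
# and across classes.
makeFolds <- function(classes, nFolds = 7L, seed = NULL) {
  cl <- factor(classes)
  n <- length(cl)
  if (n < nFolds) stop("need at least ", nFolds, " subjects", call. = FALSE)
  withSeed(seed, {
    fold <- integer(n)
    offset <- 0L
    for (lev in levels(cl)) {
      idx <- sample(which(cl == lev))
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% nFolds) + 1L
      offset <- offset + length(idx)
    }
    fold
  })
}

#' Leave-out-p cross-validation with jackknife confidence intervals
#'
#' Subjects are partitioned into `nFolds` (default 7, so p is about one
#' seventh of the subjects) class-stratified folds. An OPLS-DA sub-model is
#' fit on each leave-one-fold-out training set; its predictive loadings
#' (sign-aligned to the full model) form the jackknife sample from which a
#' delete-group jackknife standard error and a t-based confidence interval
#' are computed per variable. A variable is flagged significant when its
#' interval excludes zero. Held-out class predictions give the
#' cross-validated accuracy.
#'
#' @inheritParams fitOplsDa
#' @param nFolds number of folds (default 7).
#' @param level confidence level (default 0.95); the multiplier is the
#'   t-quantile with `nFolds - 1` degrees of freedom.
#' @param seed seed for the fold shuffle.
#' @return list of class `OplsDaCv`: `model` (full fit), `loadingTable`
#'   (data.frame: variable, loading, se, lower, upper, significant), `folds`
#'   (assignment), `cvPredictions` (data.frame: index, observed, predicted),
#'   `accuracy`.
#' @export
crossvalidateJackknife <- function(x, classes, nOrthogonal = 1L, nFolds = 7L,
                                   level = 0.95, scale = TRUE, seed = 1L) {
  x <- as.matrix(x)
  cl <- factor(classes)
  full <- fitOplsDa(x, cl, nOrthogonal, scale = scale)
  folds <- makeFolds(cl, nFolds, seed)
  vars <- names(full$preprocess$center)
  L <- matrix(NA_real_, length(vars), nFolds, dimnames = list(vars, NULL))
  pred <- character(length(cl))
  for (f in seq_len(nFolds)) {
    hold <- folds == f
    sub <- fitOplsDa(x[!hold, , drop = FALSE], cl[!hold], nOrthogonal,
                     scale = scale)
    p <- sub$loadings[match(vars, names(sub$preprocess$center))]
    # align sub-model sign with the full model
    if (sum(p * full$loadings[vars], na.rm = TRUE) < 0) p <- -p
    L[, f] <- p
    pred[hold] <- predictOplsDa(sub, x[hold, , drop = FALSE])$class
  }
  m <- nFolds
  mean_ <- rowMeans(L, na.rm = TRUE)
  se <- sqrt((m - 1) / m * rowSums((L - mean_)^2, na.rm = TRUE))
  tq <- qt(1 - (1 - level) / 2, df = m - 1)
  loading <- full$loadings
  names(loading) <- vars
  tab <- data.frame(variable = vars, loading = loading,
                    se = se, lower = loading - tq * se,
                    upper = loading + tq * se)
  tab$significant <- tab$lower > 0 | tab$upper < 0
  rownames(tab) <- NULL
  structure(list(model = full, loadingTable = tab, folds = folds,
                 cvPredictions = data.frame(index = seq_along(cl),
                                            observed = as.character(cl),
                                            predicted = pred),
                 accuracy = mean(pred == as.character(cl))),
            class = "OplsDaCv")
}

#' @export
print.OplsDaCv <- function(x, ...) {
  cat(sprintf("OplsDaCv: %d folds, CV accuracy %.1f%%, %d/%d significant variables\n",
              max(x$folds), 100 * x$accuracy, sum(x$loadingTable$significant),
              nrow(x$loadingTable)))
  invisible(x)
}
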