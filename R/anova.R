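#' @include areas.R
NULL

# Long-format (subject, group, sex, muscle, value) view of one statistic of
# the wide feature table; errors on missing cells rather than imputing.
gatherStat <- function(table, dv, extra = character(0)) {
  if (dv %in% FEATURE_STATS) {
    cols <- paste(MUSCLES, dv, sep = "_")
  } else stop("dv must be one of: ", paste(FEATURE_STATS, collapse = ", "),
              call. = FALSE)
  if (!all(cols %in% names(table)))
    stop("feature table lacks columns: ",
         paste(setdiff(cols, names(table)), collapse = ", "), call. = FALSE)
  meta <- c("subject", "group", "sex", extra)
  long <- do.call(rbind, lapply(seq_along(MUSCLES), function(j) {
    cbind(table[, meta, drop = FALSE],
          muscle = MUSCLES[j], value = table[[cols[j]]])
  }))
  long$muscle <- factor(long$muscle, levels = MUSCLES)
  long$group <- factor(long$group)
  long$sex <- factor(long$sex)
  long$subject <- factor(long$subject)
  rownames(long) <- NULL
  long
}

# k x (k-1) orthonormal within-factor contrast matrix
orthonormalContrasts <- function(k) {
  C <- stats::contr.helmert(k)
  qr.Q(qr(C))
}

# Pooled within-cell SSD (sums of squares and cross-products about the cell
# means) of a wide n x k matrix, with error df = n - #cells.
pooledSSD <- function(wide, cells) {
  cells <- droplevels(as.factor(cells))
  ssd <- matrix(0, ncol(wide), ncol(wide))
  for (lev in levels(cells)) {
    w <- wide[cells == lev, , drop = FALSE]
    if (nrow(w) > 1L) {
      cw <- sweep(w, 2L, colMeans(w))
      ssd <- ssd + crossprod(cw)
    }
  }
  list(ssd = ssd, df = nrow(wide) - nlevels(cells))
}

#' Mauchly's test of sphericity
#'
#' Tests sphericity of the orthonormal-contrast covariance of a repeated
#' measure, pooled within the between-subject cells, using the standard
#' chi-square approximation (with the second-order correction term used by
#' `stats::mauchly.test`). With two within levels sphericity holds trivially
#' (`W = 1, p = 1`).
#'
#' @param wide numeric matrix, subjects x within levels.
#' @param cells factor of between-subject cell membership (one level for a
#'   single-group design).
#' @param contrasts optional transform matrix (within levels x #contrasts);
#'   defaults to a full orthonormal contrast set.
#' @return list with `W`, `p`, `df` (chi-square df) and `errorDf`.
#' @export
mauchlyTest <- function(wide, cells = rep(1, nrow(wide)), contrasts = NULL) {
  wide <- as.matrix(wide)
  k <- ncol(wide)
  if (is.null(contrasts)) contrasts <- orthonormalContrasts(k)
  pp <- ncol(contrasts)
  if (pp < 2L)
    return(list(W = 1, p = 1, df = 0L, errorDf = NA_integer_))
  pooled <- pooledSSD(wide, cells)
  n <- pooled$df
  if (n <= pp)
    return(list(W = NA_real_, p = NA_real_, df = NA_integer_, errorDf = n))
  A <- t(contrasts) %*% pooled$ssd %*% contrasts
  trA <- sum(diag(A))
  if (trA <= 0)           # degenerate (zero-variance) contrast covariance
    return(list(W = NA_real_, p = NA_real_, df = NA_integer_, errorDf = n))
  logW <- as.numeric(determinant(A, logarithm = TRUE)$modulus -
                       pp * log(trA / pp))
  if (!is.finite(logW))   # rank-deficient contrast covariance
    return(list(W = NA_real_, p = NA_real_, df = NA_integer_, errorDf = n))
  pOrig <- pp + 1L
  rho <- 1 - (2 * pp^2 + pp + 2) / (6 * pp * n)
  w2 <- (pp + 2) * (pp - 1) * (pp - 2) *
    (2 * pp^3 + 6 * pp^2 + 3 * pOrig + 2) / (288 * (n * pp * rho)^2)
  z <- -n * rho * logW
  f <- pp * (pp + 1) / 2 - 1
  Pr1 <- pchisq(z, f, lower.tail = FALSE)
  Pr2 <- pchisq(z, f + 4, lower.tail = FALSE)
  list(W = exp(logW), p = Pr1 + w2 * (Pr2 - Pr1), df = f, errorDf = n)
}

#' Greenhouse-Geisser epsilon
#'
#' `epsilon = tr(A)^2 / (m * tr(A^2))` with `A` the orthonormal-contrast
#' SSD (pooled within between-subject cells) and `m` the number of
#' contrasts; bounded in `[1/m, 1]`, equal to 1 under exact sphericity.
#'
#' @inheritParams mauchlyTest
#' @return the epsilon estimate (1 when only one contrast exists).
#' @export
ggEpsilon <- function(wide, cells = rep(1, nrow(wide)), contrasts = NULL) {
  wide <- as.matrix(wide)
  k <- ncol(wide)
  if (is.null(contrasts)) contrasts <- orthonormalContrasts(k)
  pp <- ncol(contrasts)
  if (pp < 2L) return(1)
  pooled <- pooledSSD(wide, cells)
  A <- t(contrasts) %*% pooled$ssd %*% contrasts
  denom <- pp * sum(diag(A %*% A))
  if (denom <= 0) return(NA_real_)
  sum(diag(A))^2 / denom
}

# Parse a summary.aovlist into one data.frame of effects with stratum
# errors. Sums of squares below zeroTol are floating-point dust from a
# degenerate (zero-variance) effect: its F is forced to 0 and p to 1
# rather than reporting a 0/0 artifact.
parseAovSummary <- function(s, zeroTol = 0) {
  out <- list()
  for (stratum in names(s)) {
    tab <- s[[stratum]][[1L]]
    terms <- trimws(rownames(tab))
    resid <- terms == "Residuals"
    if (!any(resid)) next
    ssErr <- tab[resid, "Sum Sq"]; dfErr <- tab[resid, "Df"]
    for (i in which(!resid)) {
      F <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
      ss <- tab[i, "Sum Sq"]
      if (!is.finite(F) || ss <= zeroTol) { F <- 0; p <- 1 }
      eta <- if (ss > zeroTol && ss + ssErr > 0) ss / (ss + ssErr) else 0
      out[[length(out) + 1L]] <- data.frame(
        effect = terms[i], df1 = tab[i, "Df"], df2 = dfErr, ss = ss,
        ssError = ssErr, F = F, p = p, eta_p2 = eta,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# numerical floor below which a sum of squares is treated as exactly zero
ssZeroTol <- function(values) {
  n <- length(values)
  max(1e-12 * sum((values - mean(values))^2),
      1e-14 * n * (1 + mean(values)^2))
}

applyGG <- function(res, effects, eps, mauchly) {
  res$epsilon_gg <- 1
  res$mauchly_w <- NA_real_
  res$mauchly_p <- NA_real_
  res$corrected <- FALSE
  hit <- res$effect %in% effects
  res$mauchly_w[hit] <- mauchly$W
  res$mauchly_p[hit] <- mauchly$p
  if (!is.na(mauchly$p) && mauchly$p < 0.05) {
    res$epsilon_gg[hit] <- eps
    res$df1[hit] <- res$df1[hit] * eps
    res$df2[hit] <- res$df2[hit] * eps
    res$p[hit] <- ifelse(res$F[hit] > 0,
                         pf(res$F[hit], res$df1[hit], res$df2[hit],
                            lower.tail = FALSE), 1)
    res$corrected[hit] <- TRUE
  }
  res
}

#' Mixed-design repeated-measures ANOVA (group x muscle)
#'
#' Split-plot ANOVA of one deformation statistic with `group` as the
#' between-subject factor, `muscle` (five levels) as the within-subject
#' factor and, optionally, sex as an additional additive between-subject
#' factor. Fitted via `stats::aov` with an `Error(subject/muscle)` stratum
#' structure. Sphericity of the within factor is tested with
#' [mauchlyTest()]; when violated (p < 0.05) the Greenhouse-Geisser
#' correction is applied to the within and interaction degrees of freedom.
#' Partial eta-squared is `SS_effect / (SS_effect + SS_error)` within each
#' stratum.
#'
#' @param table a feature table ([buildFeatureTable()] /
#'   [simulateFeatureTable()]) restricted to one timepoint and direction.
#' @param dv one of `r paste(FEATURE_STATS, collapse = ", ")`.
#' @param adjustSex enter sex as an additive between-subject factor.
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`, `ss`,
#'   `ssError`, `F`, `p`, `eta_p2`, `epsilon_gg`, `mauchly_w`, `mauchly_p`,
#'   `corrected`.
#' @export
mixedAnova <- function(table, dv = "total", adjustSex = TRUE) {
  long <- gatherStat(table, dv)
  counts <- table(long$subject, long$muscle)
  if (any(counts != 1L))
    stop("unbalanced design: every subject needs exactly one value per muscle",
         call. = FALSE)
  if (min(table(long$group) / 5L) < 2)
    stop("need >= 2 subjects per group", call. = FALSE)
  form <- if (adjustSex && nlevels(long$sex) > 1L)
    value ~ sex + group * muscle + Error(subject / muscle)
  else value ~ group * muscle + Error(subject / muscle)
  fit <- aov(form, data = long)
  res <- parseAovSummary(summary(fit), zeroTol = ssZeroTol(long$value))

  wide <- matrix(long$value[order(long$muscle, long$subject)],
                 ncol = nlevels(long$muscle))
  subj1 <- long[!duplicated(long$subject), ]
  subj1 <- subj1[order(subj1$subject), ]
  cells <- if (adjustSex && nlevels(long$sex) > 1L)
    interaction(subj1$group, subj1$sex, drop = TRUE) else subj1$group
  mau <- mauchlyTest(wide, cells)
  eps <- ggEpsilon(wide, cells)
  applyGG(res, c("muscle", "group:muscle"), eps, mau)
}

#' Post-hoc muscle-level contrasts (Bonferroni corrected)
#'
#' Collapses the five muscles to the three anatomical levels (superficial =
#' TR/SP, middle = Scap, deep = Scerv/MF, per [MUSCLE_LEVELS]) by averaging
#' within each level per subject, then tests the level x group interaction
#' for each of the three pairwise level contrasts: the per-subject level
#' difference is compared between groups (sex-adjusted when requested).
#' p-values are Bonferroni corrected over the family of three contrasts.
#'
#' @inheritParams mixedAnova
#' @return data.frame with one row per contrast: `contrast`, `df1`, `df2`,
#'   `F`, `p`, `p_bonferroni`, `eta_p2`.
#' @export
posthocLevelContrasts <- function(table, dv = "total", adjustSex = TRUE) {
  long <- gatherStat(table, dv)
  lv <- vapply(as.character(long$muscle), function(m)
    names(MUSCLE_LEVELS)[vapply(MUSCLE_LEVELS, function(x) m %in% x, TRUE)],
    "")
  long$level <- lv
  agg <- stats::aggregate(value ~ subject + group + sex + level, long, mean)
  pairs <- utils::combn(names(MUSCLE_LEVELS), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- agg[agg$level == pairs[1L, i], ]
    b <- agg[agg$level == pairs[2L, i], ]
    b <- b[match(a$subject, b$subject), ]
    d <- data.frame(subject = a$subject, group = a$group, sex = a$sex,
                    diff = a$value - b$value)
    form <- if (adjustSex && nlevels(droplevels(d$sex)) > 1L)
      diff ~ sex + group else diff ~ group
    at <- stats::anova(lm(form, data = d))
    gi <- which(trimws(rownames(at)) == "group")
    ri <- which(trimws(rownames(at)) == "Residuals")
    F <- at[gi, "F value"]; p <- at[gi, "Pr(>F)"]
    if (!is.finite(F) || at[gi, "Sum Sq"] <= ssZeroTol(d$diff)) {
      F <- 0; p <- 1
    }
    data.frame(contrast = paste(pairs[1L, i], "vs", pairs[2L, i]),
               df1 = at[gi, "Df"], df2 = at[ri, "Df"], F = F, p = p,
               p_bonferroni = pmin(1, m * p),
               eta_p2 = if (at[gi, "Sum Sq"] + at[ri, "Sum Sq"] > 0)
                 at[gi, "Sum Sq"] / (at[gi, "Sum Sq"] + at[ri, "Sum Sq"])
               else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Within-subject repeated-measures ANOVA (timepoint x muscle)
#'
#' Two-way fully within-subject ANOVA of one deformation statistic across
#' two timepoints and the five muscles, for the subjects measured at both
#' timepoints (unpaired subjects are dropped with a message). Each within
#' effect carries its own error stratum (`Error(subject/(timepoint *
#' muscle))`); sphericity is assessed per effect on its own contrast set
#' and the Greenhouse-Geisser correction applied when Mauchly p < 0.05.
#'
#' @param table feature table containing a `timepoint` column with two
#'   levels, restricted to one direction (and typically one group).
#' @param dv one of `r paste(FEATURE_STATS, collapse = ", ")`.
#' @return data.frame as in [mixedAnova()].
#' @export
withinSubjectAnova <- function(table, dv = "total") {
  long <- gatherStat(table, dv, extra = "timepoint")
  long$timepoint <- factor(long$timepoint)
  if (nlevels(long$timepoint) != 2L)
    stop("need exactly two timepoints", call. = FALSE)
  cnt <- table(long$subject, long$timepoint)
  paired <- rownames(cnt)[cnt[, 1L] == 5L & cnt[, 2L] == 5L]
  dropped <- setdiff(levels(long$subject), paired)
  if (length(dropped)) {
    message(length(dropped), " unpaired subject(s) dropped: ",
            paste(dropped, collapse = ", "))
    long <- droplevels(long[long$subject %in% paired, ])
  }
  if (nlevels(long$subject) < 3L)
    stop("need >= 3 paired subjects", call. = FALSE)
  fit <- aov(value ~ timepoint * muscle + Error(subject / (timepoint * muscle)),
             data = long)
  res <- parseAovSummary(summary(fit), zeroTol = ssZeroTol(long$value))

  # per-effect sphericity on the subject x (timepoint, muscle) wide matrix
  long <- long[order(long$subject, long$timepoint, long$muscle), ]
  nS <- nlevels(long$subject)
  wide <- matrix(long$value, nrow = nS, byrow = TRUE)   # tp x muscle fast
  k <- nlevels(long$muscle)
  Cm <- orthonormalContrasts(k)
  Ct <- orthonormalContrasts(2L)
  ones <- function(n) matrix(1 / n, n, 1L)
  trans <- list(
    "timepoint" = kronecker(Ct, ones(k)),
    "muscle" = kronecker(ones(2L), Cm),
    "timepoint:muscle" = kronecker(Ct, Cm))
  res$epsilon_gg <- 1
  res$mauchly_w <- NA_real_
  res$mauchly_p <- NA_real_
  res$corrected <- FALSE
  for (eff in names(trans)) {
    mau <- mauchlyTest(wide, contrasts = trans[[eff]])
    eps <- ggEpsilon(wide, contrasts = trans[[eff]])
    i <- res$effect == eff
    res$mauchly_w[i] <- mau$W
    res$mauchly_p[i] <- mau$p
    if (!is.na(mau$p) && mau$p < 0.05) {
      res$epsilon_gg[i] <- eps
      res$df1[i] <- res$df1[i] * eps
      res$df2[i] <- res$df2[i] * eps
      res$p[i] <- ifelse(res$F[i] > 0,
                         pf(res$F[i], res$df1[i], res$df2[i],
                            lower.tail = FALSE), 1)
      res$corrected[i] <- TRUE
    }
  }
  res
}
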