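#' @include synth-cohort.R tracking.R areas.R anova.R multivariate.R io.R
NULL

#' Build a pipeline configuration
#'
#' Bundles the sub-configurations of every stage plus the statistics
#' options and master seed. The configuration round-trips through JSON
#' (`writePipelineConfig()` / `readPipelineConfig()`).
#'
#' @param scene a [SceneConfig-class].
#' @param motion a [MotionModel-class].
#' @param cohort a [CohortConfig-class].
#' @param tracking a [trackingConfig()].
#' @param analysisCycle rotation cycle analyzed (default the 10th, or the
#'   last cycle if fewer are simulated).
#' @param dv deformation statistic for the univariate models.
#' @param alpha significance threshold (default 0.05).
#' @param nOrthogonal orthogonal OPLS-DA components.
#' @param nFolds cross-validation folds.
#' @param seed master seed.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(scene = SceneConfig(imageSize = c(200L, 160L)),
                           motion = MotionModel(nCycles = 2, restFrames = 10,
                                                waveform = "biphasic"),
                           cohort = CohortConfig(nPerGroup = 4),
                           tracking = trackingConfig(),
                           analysisCycle = NULL, dv = "total", alpha = 0.05,
                           nOrthogonal = 1L, nFolds = 7L, seed = 1L) {
  if (is.null(analysisCycle)) analysisCycle <- min(10L, motion@nCycles)
  structure(list(scene = scene, motion = motion, cohort = cohort,
                 tracking = tracking, analysisCycle = as.integer(analysisCycle),
                 dv = dv, alpha = alpha, nOrthogonal = as.integer(nOrthogonal),
                 nFolds = as.integer(nFolds), seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Simulate -> track -> deformation curves -> area decomposition -> feature
#' table -> univariate (mixed ANOVA + post-hoc level contrasts) and
#' multivariate (PCA, OPLS-DA with jackknife CV) inference. Every stage's
#' outputs are written under `outDir` and checksummed into a run manifest.
#' A stage failure aborts with the stage and subject named.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param directions rotation directions to simulate and analyze.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
runPipeline <- function(config, outDir, directions = c("right", "left")) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- "simulate"
  files <- character(0)
  decRows <- list()
  cohort <- config$cohort
  cohort@seed <- config$seed
  subjects <- simulateCohort(cohort, config$scene, config$motion,
                             directions = directions)
  for (rec in subjects) {
    sid <- rec$meta$subject
    for (dir in directions) {
      stage <- sprintf("track (%s, %s)", sid, dir)
      entry <- rec[[dir]]
      base <- file.path(outDir, sprintf("%s_%s", sid, dir))
      writeFrameSequence(entry$sequence, paste0(base, ".tif"))
      writeGroundTruthCSV(entry$groundTruth, paste0(base, "_truth.csv"))
      files <- c(files, paste0(base, ".tif"), paste0(base, "_truth.csv"))
      rois <- defaultROIs(entry$sequence,
                          defaultLayers(amplitudes = entry$amplitudes))
      tracked <- tryCatch(
        lapply(rois, function(r)
          trackSequence(entry$sequence, r, config$tracking)),
        error = function(e) stop(sprintf("stage '%s' failed: %s", stage,
                                         conditionMessage(e)), call. = FALSE))
      stage <- sprintf("areas (%s, %s)", sid, dir)
      stats5 <- summarizeTracked(tracked, entry$sequence,
                                 cycleIndex = config$analysisCycle,
                                 direction = dir)
      decRows[[length(decRows) + 1L]] <-
        cbind(rec$meta[rep(1L, nrow(stats5)),
                       c("subject", "group", "sex", "age", "wad_grade",
                         "timepoint")],
              direction = dir, stats5)
    }
  }
  stage <- "feature table"
  dec <- do.call(rbind, decRows)
  rownames(dec) <- NULL
  table <- buildFeatureTable(dec)
  ftPath <- file.path(outDir, "feature_table.csv")
  writeFeatureTable(table, ftPath)
  files <- c(files, ftPath)

  stats <- list()
  for (dir in directions) {
    stage <- sprintf("statistics (%s)", dir)
    sub <- table[table$direction == dir, ]
    res <- tryCatch({
      an <- mixedAnova(sub, dv = config$dv)
      ph <- posthocLevelContrasts(sub, dv = config$dv)
      X <- as.matrix(sub[, featureColumns()])
      cv <- crossvalidateJackknife(X, sub$group,
                                   nOrthogonal = config$nOrthogonal,
                                   nFolds = min(config$nFolds, nrow(sub)),
                                   seed = subSeed(config$seed, 900L +
                                                    match(dir, directions)))
      list(anova = an, posthoc = ph, opls = cv)
    }, error = function(e) stop(sprintf("stage '%s' failed: %s", stage,
                                        conditionMessage(e)), call. = FALSE))
    aPath <- file.path(outDir, sprintf("anova_%s.csv", dir))
    write.csv(res$anova, aPath, row.names = FALSE)
    pPath <- file.path(outDir, sprintf("posthoc_%s.csv", dir))
    write.csv(res$posthoc, pPath, row.names = FALSE)
    lPath <- file.path(outDir, sprintf("opls_loadings_%s.csv", dir))
    write.csv(res$opls$loadingTable, lPath, row.names = FALSE)
    files <- c(files, aPath, pPath, lPath)
    stats[[dir]] <- res
  }

  stage <- "manifest"
  manifest <- list(
    package_version = as.character(utils::packageVersion("SpeckleStrain")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(writePipelineConfig(
      config, file.path(outDir, "config.json")))),
    checksums = as.list(tools::md5sum(files)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(c(manifest, list(statistics = stats, featureTable = table)))
}

#' Serialize / restore a pipeline configuration as JSON
#'
#' @param config a [pipelineConfig()].
#' @param path JSON path.
#' @return `path` for write; a `PipelineConfig` for read.
#' @export
writePipelineConfig <- function(config, path) {
  s4ToList <- function(obj) {
    sl <- methods::slotNames(class(obj))
    setNames(lapply(sl, function(nm) slot(obj, nm)), sl)
  }
  out <- list(scene = s4ToList(config$scene),
              motion = s4ToList(config$motion),
              cohort = s4ToList(config$cohort),
              tracking = unclass(config$tracking),
              analysisCycle = config$analysisCycle, dv = config$dv,
              alpha = config$alpha, nOrthogonal = config$nOrthogonal,
              nFolds = config$nFolds, seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  path
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipelineConfig(
    scene = do.call(SceneConfig, j$scene),
    motion = do.call(MotionModel, j$motion[c("nCycles", "cyclePeriodS",
                                             "restFrames", "waveform",
                                             "undershoot", "translationMm")]),
    cohort = CohortConfig(nPerGroup = j$cohort$nPerGroup,
                          groupEffects = as.data.frame(j$cohort$groupEffects),
                          betweenSubjectSd = j$cohort$betweenSubjectSd,
                          subjectCorrelation = j$cohort$subjectCorrelation,
                          timepoints = j$cohort$timepoints,
                          followupEffects = unlist(j$cohort$followupEffects),
                          seed = j$cohort$seed),
    tracking = do.call(trackingConfig, j$tracking),
    analysisCycle = j$analysisCycle, dv = j$dv, alpha = j$alpha,
    nOrthogonal = j$nOrthogonal, nFolds = j$nFolds, seed = j$seed)
}
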