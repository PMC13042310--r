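#' Run the end-to-end analysis pipeline
#'
#' Drives simulate -> (optionally render + track) -> classify -> analyze
#' for a cohort of synthetic trials, writing every table the module
#' interfaces promise plus a run manifest, deterministically for a given
#' configuration and seed.
#'
#' Stages: (1) generate \code{nFlies} trials from the scenario (fly i
#' uses seed + i); (2) optionally render each trial and re-track it from
#' pixels (slow; off by default, in which case the generated poses are
#' analyzed directly); (3) train per-behavior classifiers on the first
#' \code{trainFlies} trials using the ground-truth labels as the
#' hand-scored subset, then classify every trial and mask by the
#' annotated courtship bouts (with \code{classify = FALSE} the
#' ground-truth labels are used directly); (4) compute per-fly spatial
#' and temporal statistics and population-level circular summaries.
#'
#' @param config list with components \code{arena} (ArenaConfig),
#'   \code{scenario} (ScenarioConfig), and options: \code{outDir}
#'   (required), \code{seed} (default scenario seed), \code{nFlies},
#'   \code{classify} (logical, default TRUE), \code{track} (logical,
#'   default FALSE), \code{trainFlies} (default 8), \code{trainStride}
#'   (default 3). May also be a path to a YAML config file.
#' @return invisibly, a list with perFly, population, pathProfiles,
#'   manifestPath, and the output directory.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    cfg <- readConfig(config)
    config <- c(list(arena = cfg$arena, scenario = cfg$scenario), cfg$run)
  }
  for (field in c("arena", "scenario", "outDir"))
    if (is.null(config[[field]]))
      stop("pipeline config is missing required field: ", field)
  arena <- config$arena; scenario <- config$scenario
  if (is.na(arena@anteriorDirection))
    stop("pipeline config is missing required field: anteriorDirection ",
         "(female anterior annotation)")
  outDir <- config$outDir
  seed <- if (is.null(config$seed)) scenario@seed else config$seed
  scenario@seed <- seed
  nFlies <- if (is.null(config$nFlies)) scenario@nFlies else config$nFlies
  doClassify <- !isFALSE(config$classify)
  doTrack <- isTRUE(config$track)
  trainFlies <- if (is.null(config$trainFlies)) 8L else config$trainFlies
  trainStride <- if (is.null(config$trainStride)) 3L else config$trainStride

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  trialDir <- file.path(outDir, "trials")
  dir.create(trialDir, showWarnings = FALSE)

  logMsg("simulate: %d flies, scenario '%s', seed %d", nFlies,
         scenario@name, seed)
  trials <- generateCohort(scenario, arena, nFlies)

  if (doTrack) {
    logMsg("track: re-tracking rendered frames for %d flies", nFlies)
    trials <- lapply(seq_along(trials), function(i) {
      ren <- renderTrial(trials[[i]], arena)
      tt <- trackFrames(ren, arena)
      new("SyntheticTrial", trial = tt, labels = trials[[i]]@labels,
          scenario = scenario, flySeed = trials[[i]]@flySeed)
    })
  }

  labelsOf <- lapply(trials, trueLabels)
  if (doClassify) {
    nTrain <- min(trainFlies, nFlies)
    logMsg("classify: training on %d flies (stride %d)", nTrain, trainStride)
    ftr <- do.call(rbind, lapply(seq_len(nTrain), function(i) {
      f <- computeFeatures(trackedTrial(trials[[i]]))
      f$label <- frameLabels(trials[[i]])[
        match(f$frame, poses(trials[[i]])$frame)]
      f$trial <- sprintf("fly%03d", i)
      f[seq(1, nrow(f), by = trainStride), , drop = FALSE]
    }))
    clf <- trainClassifier(ftr, ftr$label, ftr$trial,
                           nFolds = min(4, nTrain), seed = seed)
    labelsOf <- lapply(trials, function(tr)
      classifyTrial(clf, trackedTrial(tr), boutTable(tr)))
  } else clf <- NULL

  logMsg("analyze: spatial and temporal statistics")
  perFly <- vector("list", nFlies)
  profiles <- vector("list", nFlies)
  for (i in seq_len(nFlies)) {
    tr <- trackedTrial(trials[[i]])
    lb <- labelsOf[[i]]
    sp <- spatialSummary(tr, lb)
    vp <- velocityProfile(sp$track)
    ti <- temporalIndices(lb, frameRate(tr))
    fps <- frameRate(tr)
    locRow <- unlist(lapply(COURTSHIP_ELEMENTS, function(b) {
      loc <- sp$locations[[b]]
      stats::setNames(c(loc$meanAngle, loc$R,
                        sum(lb@label == b & lb@inBout) / fps),
                      paste0(b, c("_mean_rad", "_R", "_duration_s")))
    }))
    perFly[[i]] <- cbind(
      data.frame(fly = i, seed = trials[[i]]@flySeed),
      ti,
      data.frame(d_a_mm = sp$profile@dA, d_p_mm = sp$profile@dP,
                 dadp_ratio = sp$dadp,
                 v_a_mm_s = vp$vA, v_p_mm_s = vp$vP, v_ml_mm_s = vp$vML),
      as.data.frame(as.list(locRow)))
    profiles[[i]] <- cbind(fly = i, binTable(sp$profile))
    writeTrackCsv(tr, file.path(trialDir, sprintf("fly%03d_track.csv", i)))
    writeLabelsCsv(lb, file.path(trialDir, sprintf("fly%03d_labels.csv", i)))
  }
  perFly <- do.call(rbind, perFly)
  pathProfiles <- do.call(rbind, profiles)

  population <- do.call(rbind, lapply(COURTSHIP_ELEMENTS, function(b) {
    means <- perFly[[paste0(b, "_mean_rad")]]
    durs <- perFly[[paste0(b, "_duration_s")]]
    if (sum(!is.na(means)) < 3)
      return(data.frame(element = b, n = sum(!is.na(means)),
                        mean_rad = NA, R = NA, p_unimodal = NA,
                        p_axial = NA, verdict = NA))
    ps <- populationSummary(means, durs)
    s <- ps$summary
    data.frame(element = b, n = s@n, mean_rad = s@meanAngle, R = s@R,
               p_unimodal = s@pUnimodal, p_axial = s@pAxial,
               verdict = s@verdict)
  }))

  allBouts <- do.call(rbind, lapply(seq_len(nFlies), function(i)
    cbind(fly = i, boutTable(trials[[i]]))))
  utils::write.csv(perFly, file.path(outDir, "perfly.csv"), row.names = FALSE)
  utils::write.csv(population, file.path(outDir, "population.csv"),
                   row.names = FALSE)
  utils::write.csv(pathProfiles, file.path(outDir, "path_profile.csv"),
                   row.names = FALSE)
  writeBoutsCsv(allBouts, file.path(outDir, "bouts.csv"))

  manifestPath <- file.path(outDir, "manifest.yaml")
  outputs <- c("perfly.csv", "population.csv", "path_profile.csv",
               "bouts.csv")
  manifest <- list(
    package = "flycourt",
    version = tryCatch(as.character(utils::packageVersion("flycourt")),
                       error = function(e) "unversioned"),
    seed = seed, nFlies = nFlies,
    classify = doClassify, track = doTrack,
    scenario = scenarioArgs(scenario),
    arena = list(diameter = arena@diameter, frameRate = arena@frameRate,
                 trialDuration = arena@trialDuration,
                 anteriorDirection = arena@anteriorDirection,
                 pixelScale = arena@pixelScale),
    checksums = as.list(tools::md5sum(file.path(outDir, outputs))))
  names(manifest$checksums) <- outputs
  yaml::write_yaml(manifest, manifestPath)

  invisible(list(perFly = perFly, population = population,
                 pathProfiles = pathProfiles, classifier = clf,
                 manifestPath = manifestPath, outDir = outDir))
}

logMsg <- function(fmt, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(fmt, ...))
}
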