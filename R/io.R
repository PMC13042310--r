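#' Read and write pipeline tables
#'
#' All tables are CSV with documented headers; angles are radians,
#' lengths mm, times s, with unit suffixes in the column names. Frame
#' indices are 0-based; bout intervals are half-open
#' \code{[start_frame, end_frame)}.
#'
#' @param trial a \linkS4class{TrackedTrial}.
#' @param path file path.
#' @return readers return the reconstructed object; writers return the
#'   path invisibly.
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writeTrackCsv <- function(trial, path) {
  utils::write.csv(trial@poses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @param frameRate,pixelScale,anteriorDirection trial metadata (not
#'   stored in the CSV).
#' @export
readTrackCsv <- function(path, frameRate, pixelScale = NA_real_,
                         anteriorDirection = 0) {
  p <- utils::read.csv(path)
  p$gap <- as.logical(p$gap)
  new("TrackedTrial", poses = p, frameRate = frameRate,
      pixelScale = pixelScale, anteriorDirection = anteriorDirection)
}

#' @rdname tableIO
#' @param labels a \linkS4class{BehaviorLabels}.
#' @export
writeLabelsCsv <- function(labels, path) {
  utils::write.csv(data.frame(frame = seq_along(labels@label) - 1L,
                              label = as.character(labels@label),
                              in_bout = labels@inBout),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @param bouts bout annotation data.frame.
#' @export
readLabelsCsv <- function(path, bouts) {
  d <- utils::read.csv(path)
  maskByBouts(factor(d$label, levels = BEHAVIOR_LEVELS), bouts,
              nFrames = nrow(d))
}

#' @rdname tableIO
#' @export
writeBoutsCsv <- function(bouts, path) {
  utils::write.csv(bouts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readBoutsCsv <- function(path) {
  b <- utils::read.csv(path)
  stopifnot(all(c("start_frame", "end_frame") %in% names(b)))
  b[order(b$start_frame), , drop = FALSE]
}

#' Read / write a scenario + arena configuration file
#'
#' Plain-text YAML key-value files with two top-level maps, \code{arena}
#' and \code{scenario}; unknown keys are rejected. Angular laws are maps
#' with \code{type}, \code{mu}, \code{kappa}.
#'
#' @param path file path.
#' @return \code{readConfig}: list(arena, scenario, run) where run holds
#'   any remaining top-level scalar options.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  arenaArgs <- cfg$arena
  arena <- if (is.null(arenaArgs)) arenaConfig()
           else do.call(arenaConfig, arenaArgs)
  sc <- cfg$scenario
  scenario <- if (is.null(sc)) wildtypeScenario()
  else if (!is.null(sc$preset)) {
    fn <- switch(sc$preset, wildtype = wildtypeScenario,
                 redLight = redLightScenario, headless = headlessScenario,
                 headPosterior = headPosteriorScenario,
                 whiteEyed = whiteEyedScenario,
                 stop("unknown scenario preset: ", sc$preset))
    extra <- sc[setdiff(names(sc), "preset")]
    base <- fn()
    if (length(extra)) {
      args <- scenarioArgs(base)
      args[names(extra)] <- extra
      do.call(scenarioConfig, args)
    } else base
  } else {
    if (!is.null(sc$occupancies)) sc$occupancies <- unlist(sc$occupancies)
    do.call(scenarioConfig, sc)
  }
  run <- cfg[setdiff(names(cfg), c("arena", "scenario"))]
  list(arena = arena, scenario = scenario, run = run)
}

#' @rdname readConfig
#' @param arena,scenario objects to serialize.
#' @export
writeConfig <- function(path, arena, scenario, run = list()) {
  cfg <- c(list(
    arena = list(diameter = arena@diameter, height = arena@height,
                 femalePosition = arena@femalePosition,
                 femaleBodyLength = arena@femaleBodyLength,
                 maleBodyLength = arena@maleBodyLength,
                 anteriorDirection = arena@anteriorDirection,
                 pixelScale = arena@pixelScale, frameRate = arena@frameRate,
                 trialDuration = arena@trialDuration),
    scenario = scenarioArgs(scenario)), run)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname readConfig
#' @param run named list of extra run options stored at the top level.
scenarioArgs <- function(scenario) {
  list(name = scenario@name, angularLaws = scenario@angularLaws,
       occupancies = as.list(scenario@occupancies),
       dAGen = scenario@dAGen, dPGen = scenario@dPGen,
       flankDip = scenario@flankDip, radialNoiseSd = scenario@radialNoiseSd,
       boutMeanS = scenario@boutMeanS, latencyMeanS = scenario@latencyMeanS,
       courtshipBoutMeanS = scenario@courtshipBoutMeanS,
       breakMeanS = scenario@breakMeanS, maxSpeed = scenario@maxSpeed,
       transitAngSpeed = scenario@transitAngSpeed,
       wingExtRad = scenario@wingExtRad, nFlies = scenario@nFlies,
       seed = scenario@seed)
}
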