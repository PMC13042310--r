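# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixtureCache <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# full-length wildtype cohort at the packaged study conditions
wildtypeCohort <- function() fixtureCache("cohort62", function() {
  generateCohort(wildtypeScenario(), arenaConfig())
})

# one short wildtype trial (60 s) for fast unit tests
shortTrial <- function(seed = 11) fixtureCache(paste0("short", seed), function() {
  generateTrial(wildtypeScenario(), arenaConfig(trialDuration = 60), seed)
})

# rendered + retracked 20 s trial for the tracker accuracy checks
trackedRender <- function() fixtureCache("trackedRender", function() {
  ar <- arenaConfig(trialDuration = 20)
  tr <- generateTrial(wildtypeScenario(), ar, 5)
  ren <- renderTrial(tr, ar)
  list(truth = tr, rendered = ren, tracked = trackFrames(ren, ar),
       arena = ar)
})

# build a TrackedTrial directly from pose columns (female at the origin
# unless given), for closed-form feature/statistic tests
makeTrial <- function(x, y, orientation = 0, wingL = 0.09, wingR = 0.09,
                      fx = 0, fy = 0, frameRate = 24, anterior = 0,
                      gap = FALSE) {
  n <- length(x)
  new("TrackedTrial",
      poses = data.frame(
        frame = 0:(n - 1), time_s = (0:(n - 1)) / frameRate,
        male_x_mm = x, male_y_mm = y,
        male_orientation_rad = rep_len(orientation, n),
        male_wing_l_rad = rep_len(wingL, n),
        male_wing_r_rad = rep_len(wingR, n),
        female_x_mm = fx, female_y_mm = fy,
        female_orientation_rad = anterior,
        gap = rep_len(gap, n)),
      frameRate = frameRate, pixelScale = NA_real_,
      anteriorDirection = anterior)
}

# labels object with a single courtship bout covering given frames
makeLabels <- function(labelChar, boutStart = 0, boutEnd = length(labelChar)) {
  n <- length(labelChar)
  inBout <- logical(n)
  if (boutEnd > boutStart) inBout[(boutStart + 1):boutEnd] <- TRUE
  lab <- factor(labelChar, levels = c("tapping", "scissoring", "orienting",
                                      "none"))
  lab[!inBout] <- "none"
  new("BehaviorLabels", label = lab, scores = matrix(numeric(0), 0, 3),
      inBout = inBout,
      bouts = data.frame(start_frame = boutStart, end_frame = boutEnd))
}

# per-bout circular means of a label's frames (contiguous runs)
boutMeans <- function(track, element) {
  d <- polarData(track)
  runs <- rle(as.character(d$label))
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  keep <- runs$values == element
  mapply(function(s, e) circMean(d$theta_rad[s:e]), starts[keep], ends[keep])
}
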