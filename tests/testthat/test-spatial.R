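rotateTrial <- function(trial, phi) {
  p <- trial@poses
  rot <- function(x, y) list(x = x * cos(phi) - y * sin(phi),
                             y = x * sin(phi) + y * cos(phi))
  m <- rot(p$male_x_mm, p$male_y_mm)
  f <- rot(p$female_x_mm, p$female_y_mm)
  p$male_x_mm <- m$x; p$male_y_mm <- m$y
  p$female_x_mm <- f$x; p$female_y_mm <- f$y
  p$male_orientation_rad <- wrapAngle(p$male_orientation_rad + phi)
  p$female_orientation_rad <- wrapAngle(p$female_orientation_rad + phi)
  new("TrackedTrial", poses = p, frameRate = trial@frameRate,
      pixelScale = trial@pixelScale,
      anteriorDirection = wrapAngle(trial@anteriorDirection + phi))
}

test_that("polar transform places the male relative to the female anterior", {
  ahead <- makeTrial(x = rep(4, 12), y = 0)
  expect_equal(polarData(toPolar(ahead))$theta_rad, rep(0, 12))
  behind <- makeTrial(x = rep(-4, 12), y = 0)
  expect_equal(polarData(toPolar(behind))$theta_rad, rep(pi, 12))
  noAnnot <- makeTrial(x = rep(4, 12), y = 0)
  noAnnot@anteriorDirection <- NA_real_
  expect_error(toPolar(noAnnot), "anterior")
})

test_that("spatial statistics are invariant to whole-arena rotation", {
  tr <- shortTrial()
  base <- spatialSummary(trackedTrial(tr), trueLabels(tr))
  set.seed(99)
  for (phi in runif(3, -pi, pi)) {
    rotated <- spatialSummary(rotateTrial(trackedTrial(tr), phi),
                              trueLabels(tr))
    expect_equal(rotated$profile@meanR, base$profile@meanR, tolerance = 1e-9)
    expect_equal(rotated$dadp, base$dadp, tolerance = 1e-9)
    expect_equal(rotated$locations$tapping$meanAngle,
                 base$locations$tapping$meanAngle, tolerance = 1e-9)
    expect_equal(rotated$locations$tapping$R,
                 base$locations$tapping$R, tolerance = 1e-9)
    vb <- velocityProfile(base$track); vr <- velocityProfile(rotated$track)
    expect_equal(vr$meanSideways, vb$meanSideways, tolerance = 1e-6)
  }
})

test_that("mirroring across the female axis negates angles, keeps r and R", {
  tr <- trackedTrial(shortTrial())
  p <- tr@poses
  p$male_y_mm <- -p$male_y_mm
  p$male_orientation_rad <- wrapAngle(-p$male_orientation_rad)
  mir <- new("TrackedTrial", poses = p, frameRate = tr@frameRate,
             pixelScale = tr@pixelScale, anteriorDirection = 0)
  a <- spatialSummary(tr, trueLabels(shortTrial()))
  b <- spatialSummary(mir, trueLabels(shortTrial()))
  expect_equal(b$dadp, a$dadp, tolerance = 1e-9)
  for (el in c("tapping", "orienting", "scissoring")) {
    expect_equal(b$locations[[el]]$R, a$locations[[el]]$R, tolerance = 1e-9)
    expect_equal(wrapAngle(b$locations[[el]]$meanAngle +
                           a$locations[[el]]$meanAngle), 0, tolerance = 1e-6)
  }
})

test_that("copulation-attempt removal masks exactly the injected run", {
  sc <- scenarioConfig(latencyMeanS = 0, courtshipBoutMeanS = 1e6)
  tr <- generateTrial(sc, arenaConfig(trialDuration = 60), 21)
  synth <- injectCopulationAttempt(tr, startS = 20, durationS = 60 - 25)
  track <- removeCopulationAttempts(toPolar(trackedTrial(synth),
                                            trueLabels(synth)))
  removed <- which(polarData(track)$removed)
  injected <- (20 * 24 + 1):(55 * 24)
  expect_lt(abs(min(removed) - min(injected)), 3)
  expect_lt(abs(max(removed) - max(injected)), 3)
  # a clean trial is untouched
  clean <- removeCopulationAttempts(toPolar(trackedTrial(tr),
                                            trueLabels(tr)))
  expect_false(any(polarData(clean)$removed))
})

test_that("an all-contact trial leaves the path undefined", {
  tr <- makeTrial(x = rep(2.3, 24 * 40), y = 0)
  lab <- makeLabels(rep("tapping", 24 * 40))
  track <- removeCopulationAttempts(toPolar(tr, lab))
  expect_true(all(polarData(track)$removed))
  expect_error(courtshipPath(track), "no courtship frames")
})

test_that("courtship path bins average the distances they contain", {
  # constant radius: every occupied bin reads that radius
  set.seed(4)
  th <- runif(300, -pi, pi)
  tr <- makeTrial(x = 5 * cos(th), y = 5 * sin(th))
  prof <- courtshipPath(toPolar(tr))
  expect_equal(prof@meanR[prof@counts > 0],
               rep(5, sum(prof@counts > 0)), tolerance = 1e-9)

  # two frames in known bins
  tr2 <- makeTrial(x = c(6, -4, 6, -4), y = 0)
  prof2 <- courtshipPath(toPolar(tr2))
  expect_equal(prof2@dA, 6)
  expect_equal(prof2@dP, 4)

  # brute-force group-by oracle on a synthetic trial
  trk <- toPolar(trackedTrial(shortTrial()), trueLabels(shortTrial()))
  prof3 <- courtshipPath(trk)
  d <- polarData(trk)
  keep <- d$courtship & !d$removed & !d$gap
  w <- 2 * pi / 50
  oracleBin <- ceiling((d$theta_rad[keep] + pi) / w)
  oracle <- tapply(d$r_mm[keep], factor(oracleBin, levels = 1:50), mean)
  expect_equal(unname(prof3@meanR), as.numeric(oracle), tolerance = 1e-9)
})

test_that("D_A/D_P is the ratio of the half maxima", {
  prof <- new("PathProfile", binCenter = -pi + (1:50 - 0.5) * 2 * pi / 50,
              meanR = rep(c(3.8, 5.7), 25), counts = rep(1, 50),
              dA = 5.7, dP = 3.8)
  expect_equal(dadpRatio(prof), 1.5)
  # symmetric profile: ratio 1
  sym <- courtshipPath(toPolar(makeTrial(x = 4 * cos(seq(0, 2 * pi, 0.1)),
                                         y = 4 * sin(seq(0, 2 * pi, 0.1)))))
  expect_equal(dadpRatio(sym), 1, tolerance = 1e-9)
})

test_that("swapping anterior and posterior inverts the ratio exactly", {
  tr <- shortTrial()
  a <- spatialSummary(trackedTrial(tr), trueLabels(tr))
  flipped <- trackedTrial(tr)
  flipped@anteriorDirection <- wrapAngle(flipped@anteriorDirection + pi)
  p <- flipped@poses
  p$female_orientation_rad <- wrapAngle(p$female_orientation_rad + pi)
  flipped@poses <- p
  b <- spatialSummary(flipped, trueLabels(tr))
  expect_equal(a$dadp * b$dadp, 1, tolerance = 1e-9)
})

test_that("behavior locations reduce to circular means", {
  th <- rep(pi / 3, 30)
  tr <- makeTrial(x = 4 * cos(th), y = 4 * sin(th))
  lab <- makeLabels(rep("orienting", 30))
  loc <- behaviorLocation(toPolar(tr, lab), "orienting")
  expect_equal(loc$meanAngle, pi / 3, tolerance = 1e-9)
  expect_equal(loc$R, 1, tolerance = 1e-9)

  th2 <- rep(c(pi / 2, -pi / 2), 15)
  tr2 <- makeTrial(x = 4 * cos(th2), y = 4 * sin(th2))
  loc2 <- behaviorLocation(toPolar(tr2, makeLabels(rep("tapping", 30))),
                           "tapping")
  expect_equal(loc2$R, 0, tolerance = 1e-9)

  # no frames of the element: undefined, excluded
  loc3 <- behaviorLocation(toPolar(tr2, makeLabels(rep("tapping", 30))),
                           "scissoring")
  expect_identical(loc3$n, 0L)
  expect_true(is.na(loc3$meanAngle))
})

test_that("population summaries aggregate per-fly means unweighted", {
  ps <- populationSummary(rep(0, 8), rep(1, 8))
  expect_equal(ps$arrow$length, 1)
  expect_equal(ps$arrow$angle, 0)
  u <- populationSummary(seq(-pi + 0.1, pi, length.out = 12))
  expect_lt(u$arrow$length, 0.1)
  expect_error(populationSummary(c(0, 0.2)), "at least 3")
})
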