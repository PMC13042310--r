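test_that("identical seeds give bit-identical trials", {
  sc <- wildtypeScenario()
  ar <- arenaConfig(trialDuration = 60)
  a <- generateTrial(sc, ar, 9)
  b <- generateTrial(sc, ar, 9)
  expect_identical(poses(a), poses(b))
  expect_identical(frameLabels(a), frameLabels(b))
  d <- generateTrial(sc, ar, 10)
  expect_false(identical(poses(a)$male_x_mm, poses(d)$male_x_mm))
})

test_that("realized occupancies match the configured fractions", {
  tr <- wildtypeCohort()[[1]]
  occ <- scenario(tr)@occupancies
  ib <- trueLabels(tr)@inBout
  n <- sum(ib)
  frac <- table(frameLabels(tr)[ib]) / n
  for (b in names(occ)) {
    se <- sqrt(occ[[b]] * (1 - occ[[b]]) / n)
    expect_lt(abs(frac[[b]] - occ[[b]]), 3 * se + 1e-9)
  }
})

test_that("per-behavior angular laws are recovered at the bout level", {
  tr <- wildtypeCohort()[[2]]
  track <- toPolar(trackedTrial(tr), trueLabels(tr))
  for (b in c("tapping", "orienting", "scissoring")) {
    mu <- scenario(tr)@angularLaws[[b]]$mu
    bm <- boutMeans(track, b)
    expect_gt(length(bm), 5)
    expect_lt(abs(wrapAngle(circMean(bm) - mu)), 3 * circSEM(bm))
  }
})

test_that("geometry invariants hold: in-arena, contact, bounded speed", {
  tr <- shortTrial()
  ar <- arenaConfig()
  p <- poses(tr)
  rc <- sqrt((p$male_x_mm - 0)^2 + (p$male_y_mm - 0)^2)
  expect_true(all(rc <= ar@diameter / 2))
  # non-tapping frames never closer than the contact distance
  lab <- frameLabels(tr)
  expect_true(all(rc[lab != "tapping"] >= 2.1))
  disp <- sqrt(diff(p$male_x_mm)^2 + diff(p$male_y_mm)^2)
  expect_lt(max(disp), scenario(tr)@maxSpeed / frameRate(tr))
})

test_that("degenerate concentration pins tapping angles exactly", {
  sc <- scenarioConfig(
    angularLaws = list(tapping = list(type = "vonmises", mu = pi, kappa = Inf),
                       scissoring = list(type = "vonmises", mu = 0, kappa = 1),
                       orienting = list(type = "vonmises", mu = 0, kappa = 1)),
    occupancies = c(tapping = 1, scissoring = 0, orienting = 0, none = 0),
    latencyMeanS = 0, courtshipBoutMeanS = 1e6)
  tr <- generateTrial(sc, arenaConfig(trialDuration = 30), 7)
  d <- polarData(toPolar(trackedTrial(tr), trueLabels(tr)))
  th <- d$theta_rad[d$label == "tapping"]
  expect_gt(length(th), 100)
  expect_true(all(abs(th - pi) < 1e-9))
})

test_that("a symmetric profile without flank dip is constant in angle", {
  sc <- scenarioConfig(dAGen = 4.5, dPGen = 4.5, flankDip = 0)
  th <- seq(-pi, pi, length.out = 101)
  expect_equal(radialProfile(th, sc), rep(4.5, 101))
  # and an asymmetric one interpolates monotonically with cos(theta)
  sc2 <- scenarioConfig(flankDip = 0)
  expect_equal(radialProfile(0, sc2), sc2@dAGen)
  expect_equal(radialProfile(pi, sc2), sc2@dPGen)
})

test_that("invalid occupancies are rejected", {
  expect_error(scenarioConfig(occupancies = c(tapping = 0.5, scissoring = 0.3,
                                              orienting = 0.3, none = 0.0)),
               "sum to 1")
})

test_that("wildtype tapping mean angle matches direct von Mises sampling", {
  tr <- wildtypeCohort()[[3]]
  track <- toPolar(trackedTrial(tr), trueLabels(tr))
  bm <- boutMeans(track, "tapping")
  set.seed(42)
  oracle <- rvonmises(length(bm), pi, scenario(tr)@angularLaws$tapping$kappa)
  tol <- 3 * sqrt(circSEM(bm)^2 + circSEM(oracle)^2)
  expect_lt(abs(wrapAngle(circMean(bm) - circMean(oracle))), tol)
})

test_that("synthetic feature tables share the classifier schema", {
  ft <- generateFeatureTable(wildtypeScenario(), 500, seed = 1)
  feat <- computeFeatures(trackedTrial(shortTrial()))
  expect_true(all(setdiff(names(feat), "frame") %in% names(ft)))
  expect_error(generateFeatureTable(wildtypeScenario(), 0), "nFrames")
})

test_that("separable features train to high accuracy, collapsed ones to chance", {
  sc <- wildtypeScenario()
  ft <- generateFeatureTable(sc, 6000, seed = 7)
  clf <- trainClassifier(ft, ft$label, ft$trial, nTrees = 60, seed = 7)
  expect_true(all(clf$cv$accuracy >= 0.95))

  ft0 <- generateFeatureTable(sc, 4000, seed = 8, separation = 0)
  clf0 <- trainClassifier(ft0, ft0$label, ft0$trial, nTrees = 30, seed = 8)
  for (b in clf0$cv$behavior) {
    base <- max(mean(ft0$label == b), 1 - mean(ft0$label == b))
    se <- sqrt(base * (1 - base) / nrow(ft0))
    acc <- clf0$cv$accuracy[clf0$cv$behavior == b]
    expect_lt(abs(acc - base), 5 * se)
  }
})
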