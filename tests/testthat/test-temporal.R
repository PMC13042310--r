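test_that("latency is the time of the first courtship-bout frame", {
  lab0 <- makeLabels(rep("tapping", 100), boutStart = 0, boutEnd = 100)
  expect_equal(latency(lab0, 24), 0)
  lab30 <- makeLabels(rep("none", 1000), boutStart = 720, boutEnd = 1000)
  expect_equal(latency(lab30, 24), 30)
  never <- new("BehaviorLabels",
               label = factor(rep("none", 10),
                              levels = c("tapping", "scissoring",
                                         "orienting", "none")),
               scores = matrix(numeric(0), 0, 3), inBout = rep(FALSE, 10),
               bouts = data.frame(start_frame = numeric(0),
                                  end_frame = numeric(0)))
  expect_true(is.na(latency(never, 24)))
})

test_that("a cohort recovers the generative latency distribution", {
  sc <- wildtypeScenario()
  ar <- arenaConfig()
  set.seed(1)
  lats <- vapply(1:30, function(i) {
    tr <- generateTrial(sc, ar, 500 + i)
    latency(trueLabels(tr), frameRate(tr))
  }, numeric(1))
  expect_lt(abs(mean(lats) - sc@latencyMeanS),
            3 * sc@latencyMeanS / sqrt(length(lats)))
})

test_that("indices follow their defining fractions", {
  n <- 24 * 600
  lab <- rep("none", n)
  lab[1:(n / 2)] <- "tapping"
  l <- makeLabels(lab, boutStart = 0, boutEnd = n / 2)
  ti <- temporalIndices(l, 24)
  expect_equal(ti$courtship_index, 0.5)
  expect_equal(ti$tapping_index, 1)
  expect_equal(ti$scissoring_index, 0)
  expect_equal(ti$orienting_index, 0)
})

test_that("element indices are normalized by courtship time and sum to 1", {
  tr <- shortTrial()
  ti <- temporalIndices(trueLabels(tr), frameRate(tr))
  expect_equal(ti$tapping_index + ti$scissoring_index + ti$orienting_index +
                 ti$none_index, 1, tolerance = 1e-12)
  # time accounting: latency + courting + later non-courting = trial
  lb <- trueLabels(tr)
  fps <- frameRate(tr)
  n <- length(lb@label)
  latFrames <- latency(lb, fps) * fps
  courting <- sum(lb@inBout)
  after <- n - latFrames - courting
  expect_identical(latFrames + courting + after, as.numeric(n))
  expect_gte(after, 0)
})

test_that("the three wildtype elements occupy ~90% of courtship time", {
  tr <- shortTrial(33)
  ti <- temporalIndices(trueLabels(tr), frameRate(tr))
  s <- ti$tapping_index + ti$scissoring_index + ti$orienting_index
  expect_gt(s, 0.85); expect_lt(s, 0.95)
})

test_that("sideways speed matches closed forms and the fd oracle", {
  # static male: zero everywhere
  trS <- makeTrial(x = rep(4, 30), y = 0)
  vs <- velocityProfile(toPolar(trS))
  expect_true(all(vs$meanSideways[vs$counts > 0] == 0))

  # uniform orbit: sideways speed is r * omega in every occupied bin
  omega <- 1.5; fps <- 24; r <- 4
  th <- (0:199) * omega / fps
  trO <- makeTrial(x = r * cos(th), y = r * sin(th), frameRate = fps)
  vo <- velocityProfile(toPolar(trO))
  expect_equal(vo$meanSideways[vo$counts > 0],
               rep(r * omega, sum(vo$counts > 0)), tolerance = 1e-9)
  expect_equal(vo$vA, r * omega, tolerance = 1e-9)
  expect_equal(vo$vML, r * omega, tolerance = 1e-9)

  # synthetic trial: binned means equal a brute-force recomputation
  tr <- shortTrial()
  track <- toPolar(trackedTrial(tr), trueLabels(tr))
  vp <- velocityProfile(track)
  d <- polarData(track)
  nn <- nrow(d)
  dth <- numeric(nn)
  dth[2:(nn - 1)] <- wrapAngle(d$theta_rad[3:nn] - d$theta_rad[1:(nn - 2)]) / 2
  dth[1] <- wrapAngle(d$theta_rad[2] - d$theta_rad[1])
  dth[nn] <- wrapAngle(d$theta_rad[nn] - d$theta_rad[nn - 1])
  side <- abs(d$r_mm * dth * frameRate(track))
  keep <- d$courtship & !d$removed & !d$gap
  bin <- ceiling((d$theta_rad[keep] + pi) / (2 * pi / 50))
  oracle <- tapply(side[keep], factor(bin, levels = 1:50), mean)
  got <- vp$meanSideways
  expect_equal(got[!is.na(got)], as.numeric(oracle[!is.na(oracle)]),
               tolerance = 1e-6)
})

test_that("sectors partition the circle", {
  tr <- shortTrial()
  vp <- velocityProfile(toPolar(trackedTrial(tr), trueLabels(tr)))
  inA <- abs(vp$binCenter) < pi / 4
  inP <- abs(vp$binCenter) > 3 * pi / 4
  expect_identical(sum(inA) + sum(inP) + sum(!inA & !inP), 50L)
  expect_true(all(vp$meanSideways[vp$counts > 0] >= 0))
})
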