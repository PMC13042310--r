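test_that("features hit closed forms for simple motions", {
  # static male facing the female: zero speeds, zero heading error
  tr <- makeTrial(x = rep(3, 20), y = rep(0, 20), orientation = pi)
  f <- computeFeatures(tr)
  expect_equal(f$speed_mm_s, rep(0, 20))
  expect_equal(f$heading_err_rad, rep(0, 20))
  expect_equal(f$dist_mm, rep(3, 20))
  expect_equal(f$theta_rad, rep(0, 20))

  # male on a circle about the female: constant distance feature
  th <- seq(0, 2 * pi, length.out = 50)
  tr2 <- makeTrial(x = 4 * cos(th), y = 4 * sin(th))
  f2 <- computeFeatures(tr2)
  expect_equal(f2$dist_mm, rep(4, 50), tolerance = 1e-12)
})

test_that("features equal an independent finite-difference recomputation", {
  tr <- trackedTrial(shortTrial())
  tr@poses <- tr@poses[1:200, ]
  f <- computeFeatures(tr)
  p <- tr@poses
  fps <- frameRate(tr)
  for (k in sample(2:199, 25)) {
    i <- which(f$frame == p$frame[k])
    dx <- p$female_x_mm[k] - p$male_x_mm[k]
    dy <- p$female_y_mm[k] - p$male_y_mm[k]
    expect_equal(f$dist_mm[i], sqrt(dx^2 + dy^2), tolerance = 1e-9)
    vx <- (p$male_x_mm[k + 1] - p$male_x_mm[k - 1]) / 2 * fps
    vy <- (p$male_y_mm[k + 1] - p$male_y_mm[k - 1]) / 2 * fps
    expect_equal(f$speed_mm_s[i], sqrt(vx^2 + vy^2), tolerance = 1e-9)
    d <- sqrt(dx^2 + dy^2)
    expect_equal(f$sideways_mm_s[i], abs(vx * dy / d - vy * dx / d),
                 tolerance = 1e-9)
    he <- abs(wrapAngle(p$male_orientation_rad[k] - atan2(dy, dx)))
    expect_equal(f$heading_err_rad[i], he, tolerance = 1e-9)
  }
  # windowed feature: plain mean over the +-5 frame window
  i <- which(f$frame == p$frame[100])
  expect_equal(f$win_dist_mm[i], mean(f$dist_mm[(i - 5):(i + 5)]),
               tolerance = 1e-9)
})

test_that("an all-gap trial yields an empty feature table", {
  tr <- makeTrial(x = rep(3, 20), y = 0, gap = TRUE)
  expect_identical(nrow(computeFeatures(tr)), 0L)
  expect_error(computeFeatures(makeTrial(x = rep(3, 5), y = 0)), "at least")
})

test_that("the precedence hierarchy is tapping > scissoring > orienting", {
  sc <- matrix(c(1, 1, 1,
                 -1, 1, 1,
                 -1, -1, 1,
                 -1, -1, -1), 4, 3, byrow = TRUE,
               dimnames = list(NULL, c("tapping", "scissoring", "orienting")))
  lab <- applyHierarchy(sc)
  expect_identical(as.character(lab),
                   c("tapping", "scissoring", "orienting", "none"))
  # idempotent at the label level, and exactly one label per frame
  expect_identical(applyHierarchy(lab), lab)
  expect_false(anyNA(lab))
})

test_that("bout masking discards exactly the out-of-bout positives", {
  lab <- factor(rep(c("tapping", "orienting"), 50),
                levels = c("tapping", "scissoring", "orienting", "none"))
  # empty bout list: everything none
  none <- maskByBouts(lab, data.frame(start_frame = numeric(0),
                                      end_frame = numeric(0)))
  expect_true(all(none@label == "none"))
  # all-trial bout: unchanged
  full <- maskByBouts(lab, data.frame(start_frame = 0, end_frame = 100))
  expect_identical(full@label, lab)
  # partial bout: discarded count equals the brute-force count
  bouts <- data.frame(start_frame = c(10, 60), end_frame = c(30, 80))
  masked <- maskByBouts(lab, bouts)
  inb <- rep(FALSE, 100); inb[c(11:30, 61:80)] <- TRUE
  expect_identical(masked@inBout, inb)
  expect_identical(sum(masked@label == "none") - sum(lab == "none"),
                   sum(!inb & lab != "none"))
  expect_error(maskByBouts(lab, data.frame(start_frame = 0, end_frame = 101)),
               "beyond trial length")
})

test_that("training refuses degenerate label sets", {
  ft <- generateFeatureTable(wildtypeScenario(), 400, seed = 3)
  allSame <- factor(rep("tapping", nrow(ft)),
                    levels = levels(ft$label))
  expect_error(trainClassifier(ft, allSame, ft$trial), "single class")
  noSciss <- ft$label
  noSciss[noSciss == "scissoring"] <- "none"
  expect_error(trainClassifier(ft, noSciss, ft$trial),
               "scissoring")
})

test_that("classifier labels recover ground truth on held-out trials", {
  sc <- wildtypeScenario()
  ar <- arenaConfig(trialDuration = 120)
  trials <- lapply(1:6, function(i) generateTrial(sc, ar, 300 + i))
  ftr <- do.call(rbind, lapply(1:4, function(i) {
    f <- computeFeatures(trackedTrial(trials[[i]]))
    f$label <- frameLabels(trials[[i]])[match(f$frame,
                                              poses(trials[[i]])$frame)]
    f$trial <- paste0("T", i)
    f[seq(1, nrow(f), by = 2), ]
  }))
  clf <- trainClassifier(ftr, ftr$label, ftr$trial, seed = 1)
  agree <- vapply(5:6, function(i) {
    pred <- classifyTrial(clf, trackedTrial(trials[[i]]),
                          boutTable(trials[[i]]))
    # mutual exclusivity is asserted on every pipeline run
    expect_false(anyNA(pred@label))
    mean(pred@label == frameLabels(trials[[i]]))
  }, numeric(1))
  expect_true(all(agree >= 0.9))
})
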