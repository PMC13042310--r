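cleanBg <- function(arena) {
  npx <- ceiling(arena@diameter * arena@pixelScale)
  matrix(230, npx, npx)
}

test_that("renderer and pose fit agree on a single known frame", {
  ar <- arenaConfig(trialDuration = 1)
  tr <- makeTrial(x = 4.2, y = -1.3, orientation = 0.7)
  ren <- renderTrial(tr, ar, frames = 0)
  comps <- segmentFlies(ren$frames[, , 1], cleanBg(ar))
  expect_length(comps, 2)
  fits <- lapply(comps, fitPose, pixelScale = ar@pixelScale)
  cent <- vapply(fits, function(f) c(f$cx, f$cy), numeric(2))
  # one fit matches the male's ground-truth centroid within 0.5 px
  errs <- sqrt((cent[1, ] - ren$truth$male_cx_px)^2 +
               (cent[2, ] - ren$truth$male_cy_px)^2)
  expect_lt(min(errs), 0.5)
  male <- fits[[which.min(errs)]]
  axErr <- abs(wrapAngle(2 * (male$axisAngle - 0.7))) / 2  # axis mod pi
  expect_lt(axErr, 3 * pi / 180)
})

test_that("an empty frame request yields an empty stack and table", {
  ar <- arenaConfig(trialDuration = 1)
  ren <- renderTrial(makeTrial(4, 0), ar, frames = integer(0))
  expect_identical(dim(ren$frames)[3], 0L)
  expect_identical(nrow(ren$truth), 0L)
})

test_that("folded wings render a bilaterally symmetric blob", {
  ar <- arenaConfig(trialDuration = 1)
  # male on the x axis heading +x, wings exactly 0: symmetric about y = 0
  tr <- makeTrial(x = 5, y = 0, orientation = 0, wingL = 0, wingR = 0)
  ren <- renderTrial(tr, ar, frames = 0)
  img <- ren$frames[, , 1]
  expect_identical(img, img[nrow(img):1, ])
})

test_that("segmentation counts components and flags contact", {
  ar <- arenaConfig(trialDuration = 1)
  bg <- cleanBg(ar)
  expect_length(segmentFlies(bg, bg), 0)

  tr <- renderTrial(makeTrial(5, 0), ar, frames = 0)
  expect_length(segmentFlies(tr$frames[, , 1], bg), 2)

  # tapping contact: blobs merge into one component
  touching <- renderTrial(makeTrial(2.0, 0), ar, frames = 0)
  expect_length(segmentFlies(touching$frames[, , 1], bg), 1)
})

test_that("a perfectly circular blob has undefined orientation", {
  npx <- 101
  cx <- 50.5
  idx <- which(outer(seq_len(npx) - 0.5 - cx, seq_len(npx) - 0.5 - cx,
                     function(a, b) a^2 + b^2) <= 8^2, arr.ind = TRUE)
  comp <- list(px = idx[, 2], py = idx[, 1])
  expect_true(is.na(fitPose(comp, 10)$axisAngle))
})

test_that("an extended wing is measured at its drawn angle", {
  ar <- arenaConfig(trialDuration = 1)
  tr <- makeTrial(x = 5, y = 0, orientation = 0.4, wingL = pi / 3,
                  wingR = 0.05)
  ren <- renderTrial(tr, ar, frames = 0)
  comps <- segmentFlies(ren$frames[, , 1], cleanBg(ar))
  fits <- lapply(comps, fitPose, pixelScale = ar@pixelScale)
  male <- fits[[which.max(vapply(fits, `[[`, numeric(1), "wingL"))]]
  expect_lt(abs(male$wingL - pi / 3), 5 * pi / 180)
})

test_that("tracking a rendered trial meets the accuracy floor", {
  fx <- trackedRender()
  p <- poses(fx$tracked); q <- poses(fx$truth)
  ok <- !p$gap
  expect_gt(mean(ok), 0.98)
  cenRMSE <- sqrt(mean((p$male_x_mm[ok] - q$male_x_mm[ok])^2 +
                       (p$male_y_mm[ok] - q$male_y_mm[ok])^2))
  expect_lt(cenRMSE, 0.1)
  angErr <- wrapAngle(p$male_orientation_rad[ok] - q$male_orientation_rad[ok])
  expect_lt(sqrt(mean(angErr^2)), 5 * pi / 180)
  wErr <- c(p$male_wing_l_rad[ok] - q$male_wing_l_rad[ok],
            p$male_wing_r_rad[ok] - q$male_wing_r_rad[ok])
  expect_lt(sqrt(mean(wErr^2)), 8 * pi / 180)
  # identity: the female track sits at her true fixed position
  expect_lt(abs(p$female_x_mm[1] - q$female_x_mm[1]), 0.1)
  expect_lt(abs(p$female_y_mm[1] - q$female_y_mm[1]), 0.1)
})

test_that("pixel/mm mapping round-trips exactly", {
  ar <- arenaConfig()
  mm <- c(-4.25, 0, 7.125)
  px <- (mm + ar@diameter / 2) * ar@pixelScale
  expect_equal(px / ar@pixelScale - ar@diameter / 2, mm)
})

test_that("frame stacks round-trip through PNG files", {
  ar <- arenaConfig(trialDuration = 1)
  ren <- renderTrial(makeTrial(c(5, 5.2), c(0, 0.1)), ar, frames = 0:1)
  dir <- withr::local_tempdir()
  writeFrames(ren, dir)
  back <- readFrames(dir)
  expect_equal(back$frames, ren$frames, tolerance = 1 / 255)
  expect_identical(back$frameNumbers, 0:1)
})

test_that("a static male's heading comes from the wing-side prior", {
  ar <- arenaConfig(trialDuration = 1)
  tr <- makeTrial(x = rep(5, 12), y = rep(0, 12), orientation = 2.2)
  ren <- renderTrial(tr, ar, frames = 0:11)
  tt <- trackFrames(ren, ar, background = cleanBg(ar))
  err <- wrapAngle(poses(tt)$male_orientation_rad - 2.2)
  expect_lt(max(abs(err)), 5 * pi / 180)
})

test_that("an injected heading flip is removed by the continuity pass", {
  axis <- rep(0.5, 40)
  axis[20] <- wrapAngle(0.5 + pi)          # single flipped frame
  cx <- cumsum(rep(2, 40)) * cos(0.5)      # walking along its heading
  cy <- cumsum(rep(2, 40)) * sin(0.5)
  h <- resolveHeading(axis, cx, cy, hint = rep(NA_real_, 40),
                      mmPerFramePerPx = 24 / 10)
  expect_true(all(abs(wrapAngle(h - 0.5)) < 1e-9))
})

test_that("two mobile tracks are a hard assay error", {
  ar <- arenaConfig(trialDuration = 1)
  n <- 30
  # both blobs translate together: shift each rendered frame progressively
  base <- renderTrial(makeTrial(5, 0), ar, frames = 0)$frames[, , 1]
  npx <- nrow(base)
  stack <- array(230, dim = c(npx, npx, n))
  for (k in seq_len(n)) {
    sh <- (k - 1) * 2
    stack[, (1 + sh):npx, k] <- base[, 1:(npx - sh)]
  }
  expect_error(trackFrames(stack, ar, background = cleanBg(ar)),
               "both tracks are mobile")
})
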