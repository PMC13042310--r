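#' Generate a synthetic courtship trial
#'
#' Simulates a male courting a fixed female with the statistical structure
#' the downstream analysis assumes, together with ground-truth per-frame
#' behavior labels and courtship-bout annotations.
#'
#' The timeline is courtship latency (exponential), then alternating
#' courtship bouts and breaks. Within courtship, behavior bouts with
#' exponential durations alternate; each bout draws an anchor angle from
#' its behavior's angular law, the male moves to the anchor at a bounded
#' angular speed (these approach frames belong to the bout) and then holds
#' with a small autoregressive angular jitter. The male-female distance
#' follows the scenario's radial profile (\code{\link{radialProfile}})
#' plus smooth autoregressive noise on every courtship frame; outside
#' courtship the male wanders at larger radii. During courtship elements
#' the male faces the female (he sidesteps while moving); during "none"
#' frames his heading follows his direction of motion. Scissoring extends
#' one wing to the scenario's wing-extension angle. Consecutive-frame
#' displacements are rate-limited so the configured maximum speed is
#' respected, and identical (scenario, arena, flySeed) inputs give
#' bit-identical output.
#'
#' @param scenario a \linkS4class{ScenarioConfig}.
#' @param arena an \linkS4class{ArenaConfig}.
#' @param flySeed integer seed for this fly.
#' @return a \linkS4class{SyntheticTrial}.
#' @examples
#' tr <- generateTrial(wildtypeScenario(), arenaConfig(trialDuration = 30), 1)
#' table(frameLabels(tr))
#' @export
generateTrial <- function(scenario, arena, flySeed) {
  validObject(scenario); validObject(arena)
  occ <- scenario@occupancies
  if (abs(sum(occ) - 1) > 1e-9)
    stop("occupancies must sum to 1 within 1e-9")
  if (scenario@dAGen <= arena@femaleBodyLength / 2 ||
      scenario@dPGen <= arena@femaleBodyLength / 2)
    stop("dAGen and dPGen must exceed half the female body length")
  set.seed(as.integer(flySeed))

  fps <- arena@frameRate
  n <- round(arena@trialDuration * fps)
  rmax <- arena@diameter / 2 - arena@maleBodyLength / 2 - 0.05
  rmin <- (arena@femaleBodyLength + arena@maleBodyLength) / 2 * 0.85
  minBout <- max(3L, round(0.25 * fps))

  label <- integer(n)            # index into BEHAVIOR_LEVELS; 4 = none
  inBout <- logical(n)
  theta <- numeric(n)
  wingL <- numeric(n); wingR <- numeric(n)
  headOff <- rep(NA_real_, n)    # heading offset from the to-female direction
                                 # (NA = heading follows motion direction)

  ## -- timeline: latency, then alternating courtship bouts and breaks -----
  lat <- if (scenario@latencyMeanS <= 0) 0L else
    min(round(fps * stats::rexp(1, 1 / scenario@latencyMeanS)), round(n / 2))
  segs <- list()                 # list of c(start, end, isCourtship), 1-based
  cur <- lat + 1L
  if (lat > 0) segs[[1]] <- c(1L, lat, 0L)
  courting <- TRUE
  while (cur <= n) {
    mean_s <- if (courting) scenario@courtshipBoutMeanS else scenario@breakMeanS
    len <- max(round(fps * stats::rexp(1, 1 / mean_s)), round(2 * fps))
    end <- min(cur + len - 1L, n)
    segs[[length(segs) + 1L]] <- c(cur, end, as.integer(courting))
    cur <- end + 1L
    courting <- !courting
  }

  ## -- behavior-bout scheduler (quota-balancing with side stickiness) ----
  # realized courtship frames per behavior, used to steer occupancies to
  # their targets within about one bout length
  realized <- stats::setNames(numeric(4), BEHAVIOR_LEVELS)
  assignedCourt <- 0
  stickyBonus <- 0.75 * scenario@boutMeanS * fps
  behSide <- vapply(BEHAVIOR_LEVELS, function(b) {
    if (b == "none") return(0)
    mu <- scenario@angularLaws[[b]]$mu
    if (cos(mu) >= 0) 1 else -1
  }, numeric(1))

  curTheta <- NA_real_           # set at the first courtship bout
  rEstState <- NA_real_          # running rate-limited radius estimate (mm)
  maxStep <- 0.4 * scenario@maxSpeed / fps   # radial rate limit, mm/frame
  wingBase <- 0.09               # folded-wing resting angle (rad)
  wanderR <- rep(NA_real_, n)
  ar1 <- function(m, sd, rho, init = 0) {
    if (m == 0) return(numeric(0))
    as.numeric(stats::filter(stats::rnorm(m, 0, sd * sqrt(1 - rho^2)),
                             rho, method = "recursive", init = init))
  }
  # forward rate limiter: follow x with per-frame changes bounded by maxd
  rateLimit <- function(x, maxd) {
    y <- x
    for (k in seq_along(x)[-1]) {
      d <- x[k] - y[k - 1]
      y[k] <- y[k - 1] + sign(d) * min(abs(d), maxd)
    }
    y
  }

  # single chronological pass so positions stay continuous across the
  # courtship/break boundaries
  for (seg in segs) {
    s <- seg[1]; e <- seg[2]
    if (seg[3] == 0L) {
      ## non-courtship wandering
      m <- e - s + 1L
      label[s:e] <- 4L
      th0 <- if (is.na(curTheta)) stats::runif(1, -pi, pi) else curTheta
      # mean-reverting wander radius, clamped inside the arena
      rw <- numeric(m)
      r0 <- if (is.na(rEstState)) 8 else rEstState
      eps <- stats::rnorm(m, 0, 0.3)
      for (k in seq_len(m)) {
        r0 <- r0 + 0.02 * (8 - r0) + eps[k]
        r0 <- min(max(r0, rmin + 0.3), rmax)
        rw[k] <- r0
      }
      wanderR[s:e] <- rw
      # angular walk with arc-length steps bounded at 0.5 mm/frame
      darc <- pmin(pmax(ar1(m, 0.4, 0.9), -0.5), 0.5)
      theta[s:e] <- wrapAngle(th0 + cumsum(darc / rw))
      curTheta <- theta[e]; rEstState <- rw[m]
      next
    }

    inBout[s:e] <- TRUE
    pos <- s
    while (pos <= e) {
      segLeft <- e - pos + 1L
      # pick the behavior with the largest occupancy deficit, with a bonus
      # for staying on the male's current side of the female
      deficit <- occ * (assignedCourt + scenario@boutMeanS * fps) - realized
      if (!is.na(curTheta)) {
        side <- if (cos(curTheta) >= 0) 1 else -1
        deficit <- deficit + stickyBonus * (behSide == side) * (occ > 0)
      }
      deficit[occ == 0] <- -Inf
      b <- which.max(deficit)
      bname <- BEHAVIOR_LEVELS[b]
      L <- max(round(fps * stats::rexp(1, 1 / scenario@boutMeanS)), minBout)
      L <- min(L, segLeft)
      if (segLeft - L < minBout) L <- segLeft   # absorb stub frames

      law <- scenario@angularLaws[[bname]]
      anchor <- if (bname == "none") stats::runif(1, -pi, pi)
                else sampleAngularLaw(1, law)
      if (is.na(curTheta)) curTheta <- anchor
      if (is.na(rEstState)) rEstState <- radialProfile(curTheta, scenario)

      idx <- pos:(pos + L - 1L)
      label[idx] <- b
      realized[b] <- realized[b] + L
      assignedCourt <- assignedCourt + L

      # approach: rotate toward the anchor at an angular speed bounded by
      # the configured transit speed and by the (rate-limited) current
      # radius, so tangential displacement stays under the speed cap
      th <- numeric(L)
      i <- 1L
      delta <- wrapAngle(anchor - curTheta)
      while (i <= L && abs(delta) > 1e-9) {
        rTar <- max(radialProfile(curTheta, scenario), rmin)
        rEstState <- rEstState + sign(rTar - rEstState) *
          min(abs(rTar - rEstState), maxStep)
        step <- min(scenario@transitAngSpeed,
                    0.6 * scenario@maxSpeed / max(rEstState, rmin)) / fps
        if (abs(delta) <= step) {
          curTheta <- wrapAngle(anchor); delta <- 0
        } else {
          curTheta <- wrapAngle(curTheta + sign(delta) * step)
          delta <- wrapAngle(anchor - curTheta)
        }
        th[i] <- curTheta
        i <- i + 1L
      }
      if (i <= L) {
        hold <- L - i + 1L
        kap <- law$kappa
        sdHold <- switch(bname, tapping = 0.15, none = 0.25, 0.03)
        if (bname != "none" && is.infinite(kap)) sdHold <- 0
        j <- if (sdHold > 0) ar1(hold, sdHold, 0.9) else numeric(hold)
        # bound the tangential jitter speed at the bout's working radius;
        # the leading 0 keeps the first hold frame continuous with the
        # approach arrival
        rAnchor <- max(radialProfile(anchor, scenario), rmin)
        j <- rateLimit(c(0, j), 0.55 / rAnchor)[-1]
        th[i:L] <- wrapAngle(anchor + j)
        curTheta <- th[L]
        rTar <- max(radialProfile(anchor, scenario), rmin)
        rEstState <- rTar + sign(rEstState - rTar) *
          max(0, abs(rEstState - rTar) - hold * maxStep)
      }
      theta[idx] <- th

      # heading: elements face the female (small offset); none follows motion
      if (bname != "none") headOff[idx] <- 0

      # wings: scissoring extends one wing, otherwise folded
      if (bname == "scissoring") {
        sideW <- stats::runif(1) < 0.5
        ext <- pmax(0, scenario@wingExtRad + ar1(L, 0.06, 0.9))
        if (sideW) wingL[idx] <- ext else wingR[idx] <- ext
      }
      pos <- pos + L
    }
  }

  ## -- radius: profile + smooth noise on courtship frames, rate-limited --
  rnoise <- ar1(n, scenario@radialNoiseSd, 0.95)
  rTarget <- ifelse(inBout, radialProfile(theta, scenario) + rnoise, wanderR)
  rTarget <- pmin(pmax(rTarget, rmin), rmax)
  r <- rTarget
  maxStep <- 0.4 * scenario@maxSpeed / fps
  for (k in 2:n) {
    d <- rTarget[k] - r[k - 1]
    r[k] <- r[k - 1] + sign(d) * min(abs(d), maxStep)
  }

  ## -- positions, headings, wings ----------------------------------------
  fx <- arena@femalePosition[1]; fy <- arena@femalePosition[2]
  phi <- arena@anteriorDirection + theta
  x <- fx + r * cos(phi)
  y <- fy + r * sin(phi)

  toFemale <- atan2(fy - y, fx - x)
  headNoise <- ar1(n, 0.06, 0.9)
  heading <- numeric(n)
  faceIdx <- !is.na(headOff)
  heading[faceIdx] <- toFemale[faceIdx] + headNoise[faceIdx]
  # "none" frames: heading follows the direction of motion
  dx <- c(0, diff(x)); dy <- c(0, diff(y))
  motionDir <- atan2(dy, dx)
  still <- sqrt(dx^2 + dy^2) < 1e-3
  for (k in seq_len(n)) if (still[k]) motionDir[k] <- if (k > 1) motionDir[k - 1] else 0
  heading[!faceIdx] <- motionDir[!faceIdx] + headNoise[!faceIdx]
  # flies turn smoothly: follow the target heading at a bounded turn rate
  maxTurn <- 0.6                       # rad/frame
  for (k in 2:n) {
    d <- wrapAngle(heading[k] - heading[k - 1])
    heading[k] <- heading[k - 1] + sign(d) * min(abs(d), maxTurn)
  }
  heading <- wrapAngle(heading)

  wjit <- abs(ar1(n, 0.03, 0.9))
  wingL <- pmin(pmax(ifelse(wingL > 0, wingL, wingBase + wjit), 0), pi - 1e-6)
  wingR <- pmin(pmax(ifelse(wingR > 0, wingR, wingBase + wjit), 0), pi - 1e-6)

  pose <- data.frame(
    frame = 0:(n - 1), time_s = (0:(n - 1)) / fps,
    male_x_mm = x, male_y_mm = y, male_orientation_rad = heading,
    male_wing_l_rad = wingL, male_wing_r_rad = wingR,
    female_x_mm = fx, female_y_mm = fy,
    female_orientation_rad = wrapAngle(arena@anteriorDirection),
    gap = FALSE)

  courtSegs <- Filter(function(s) s[3] == 1L, segs)
  bouts <- if (length(courtSegs))
    data.frame(start_frame = vapply(courtSegs, `[`, numeric(1), 1) - 1,
               end_frame = vapply(courtSegs, `[`, numeric(1), 2))
  else data.frame(start_frame = numeric(0), end_frame = numeric(0))

  labels <- new("BehaviorLabels",
                label = factor(BEHAVIOR_LEVELS[label], levels = BEHAVIOR_LEVELS),
                scores = matrix(numeric(0), 0, 3), inBout = inBout,
                bouts = bouts)
  trial <- new("TrackedTrial", poses = pose, frameRate = fps,
               pixelScale = NA_real_,
               anteriorDirection = arena@anteriorDirection)
  new("SyntheticTrial", trial = trial, labels = labels, scenario = scenario,
      flySeed = flySeed)
}

#' Generate a cohort of synthetic trials
#'
#' Fly i uses seed \code{scenario@seed + i}, so a cohort is reproducible
#' from the scenario alone.
#'
#' @param scenario a \linkS4class{ScenarioConfig}.
#' @param arena an \linkS4class{ArenaConfig}.
#' @param nFlies number of flies (default \code{scenario@nFlies}).
#' @return a list of \linkS4class{SyntheticTrial}.
#' @export
generateCohort <- function(scenario, arena = arenaConfig(),
                           nFlies = scenario@nFlies) {
  lapply(seq_len(nFlies), function(i)
    generateTrial(scenario, arena, scenario@seed + i))
}

#' Inject a copulation-attempt bout into a synthetic trial
#'
#' Overwrites a frame range inside a courtship bout with a long low-motion
#' contact: the male sits at contact distance from the female with
#' negligible jitter, facing her. Used to exercise
#' \code{\link{removeCopulationAttempts}}.
#'
#' @param synth a \linkS4class{SyntheticTrial}.
#' @param startS,durationS start time and duration (s).
#' @param contactR centroid distance during the attempt (mm).
#' @return the modified \linkS4class{SyntheticTrial}.
#' @export
injectCopulationAttempt <- function(synth, startS, durationS,
                                    contactR = 2.3) {
  fps <- synth@trial@frameRate
  p <- synth@trial@poses
  i0 <- round(startS * fps) + 1L
  i1 <- min(round((startS + durationS) * fps), nrow(p))
  if (i0 >= i1) stop("empty injection range")
  if (!all(synth@labels@inBout[i0:i1]))
    stop("injection range must lie inside a courtship bout")
  idx <- i0:i1
  fx <- p$female_x_mm[1]; fy <- p$female_y_mm[1]
  th <- atan2(p$male_y_mm[i0] - fy, p$male_x_mm[i0] - fx)
  p$male_x_mm[idx] <- fx + contactR * cos(th) + stats::rnorm(length(idx), 0, 0.002)
  p$male_y_mm[idx] <- fy + contactR * sin(th) + stats::rnorm(length(idx), 0, 0.002)
  p$male_orientation_rad[idx] <- wrapAngle(th + pi)
  synth@trial@poses <- p
  lab <- synth@labels@label
  lab[idx] <- "tapping"
  synth@labels@label <- lab
  synth
}
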