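#' Generate a labeled synthetic feature table
#'
#' Draws per-frame feature vectors directly from documented per-class
#' distributions, with the same column schema as
#' \code{\link{computeFeatures}}, for classifier training and validation
#' without rendering or tracking. Class frequencies follow the scenario's
#' occupancies; angular positions follow the scenario's angular laws; the
#' distance feature follows the scenario's radial profile at the drawn
#' angle. Kinematic and wing features are Gaussian per class around the
#' behaviors' defining signatures (tapping moves at moderate speed close
#' to the female facing her; scissoring and orienting are static and
#' facing, scissoring with one wing extended; "none" moves with a large
#' heading error). At the default \code{separation = 1} the classes are
#' separable by construction; \code{separation = 0} collapses every class
#' onto the pooled distribution (useful as a chance-level control).
#'
#' @param scenario a \linkS4class{ScenarioConfig}.
#' @param nFrames number of frames (> 0).
#' @param seed RNG seed.
#' @param separation class-separation multiplier in [0, 1].
#' @param nTrials number of pseudo-trials the frames are split into
#'   (grouping unit for grouped CV), default 8.
#' @return data.frame with columns trial, frame, label and the feature
#'   schema of \code{\link{computeFeatures}}.
#' @export
generateFeatureTable <- function(scenario, nFrames, seed = 1,
                                 separation = 1, nTrials = 8) {
  if (nFrames <= 0) stop("nFrames must be > 0")
  stopifnot(separation >= 0, separation <= 1)
  set.seed(as.integer(seed))
  occ <- scenario@occupancies
  lab <- factor(sample(BEHAVIOR_LEVELS, nFrames, replace = TRUE, prob = occ),
                levels = BEHAVIOR_LEVELS)
  n <- nFrames
  s <- separation

  # angular position: behavior law with concentration scaled by s
  theta <- numeric(n)
  for (b in BEHAVIOR_LEVELS) {
    i <- which(lab == b)
    if (!length(i)) next
    if (b == "none") theta[i] <- stats::runif(length(i), -pi, pi)
    else {
      law <- scenario@angularLaws[[b]]
      law$kappa <- law$kappa * s
      theta[i] <- sampleAngularLaw(length(i), law)
    }
  }
  dist <- radialProfile(theta, scenario) +
    stats::rnorm(n, 0, scenario@radialNoiseSd)

  # per-class means for the scalar features; blended toward the pooled
  # mean by (1 - separation)
  classMean <- function(tap, sci, ori, non) {
    v <- c(tapping = tap, scissoring = sci, orienting = ori, none = non)
    g <- sum(v * occ)
    g + s * (v - g)
  }
  draw <- function(means, sds) {
    mu <- means[as.character(lab)]
    sd <- sds[as.character(lab)]
    stats::rnorm(n, mu, sd)
  }
  # class-conditional sds are blended toward the pooled sd as well, so
  # separation = 0 makes the classes exactly exchangeable
  sds <- function(tap, sci, ori, non) {
    v <- c(tapping = tap, scissoring = sci, orienting = ori, none = non)
    g <- sum(v * occ)
    g + s * (v - g)
  }

  speed <- pmax(draw(classMean(5, 0.15, 0.15, 8), sds(1.5, 0.08, 0.08, 2.5)), 0)
  sideways <- pmax(speed * stats::runif(n, 0.55, 0.95) +
                     stats::rnorm(n, 0, 0.1), 0)
  angspeed <- pmax(draw(classMean(1.2, 0.3, 0.3, 2.0), sds(0.5, 0.15, 0.15, 0.8)), 0)
  headErr <- pmin(pmax(draw(classMean(0.12, 0.10, 0.10, 1.6),
                            sds(0.08, 0.06, 0.06, 0.5)), 0), pi)
  wingExt <- pmax(draw(classMean(0.09, scenario@wingExtRad, 0.09, 0.09),
                       sds(0.05, 0.10, 0.05, 0.05)), 0)
  wingFold <- pmax(stats::rnorm(n, 0.09, 0.05), 0)
  leftIsExt <- stats::runif(n) < 0.5
  wl <- ifelse(leftIsExt, wingExt, wingFold)
  wr <- ifelse(leftIsExt, wingFold, wingExt)
  ddist <- stats::rnorm(n, 0, 0.15 + 0.12 * speed)

  winNoise <- function(x, frac = 1 / 3)
    x + stats::rnorm(n, 0, pmax(stats::sd(x) * frac, 1e-6) / sqrt(11))
  out <- data.frame(
    trial = rep_len(paste0("T", seq_len(nTrials)), n),
    frame = seq_len(n) - 1L, label = lab,
    dist_mm = dist, ddist_mm_s = ddist, speed_mm_s = speed,
    sideways_mm_s = sideways, angspeed_rad_s = angspeed,
    heading_err_rad = headErr, theta_rad = theta, cos_theta = cos(theta),
    wing_l_rad = wl, wing_r_rad = wr, wing_max_rad = pmax(wl, wr),
    win_dist_mm = winNoise(dist), win_speed_mm_s = winNoise(speed),
    win_sideways_mm_s = winNoise(sideways),
    win_angspeed_rad_s = winNoise(angspeed),
    win_heading_err_rad = winNoise(headErr),
    win_wing_max_rad = winNoise(pmax(wl, wr)))
  out
}
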