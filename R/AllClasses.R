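#' @import methods
NULL

BEHAVIOR_LEVELS <- c("tapping", "scissoring", "orienting", "none")
COURTSHIP_ELEMENTS <- c("tapping", "scissoring", "orienting")

#' Arena and recording configuration
#'
#' Physical and recording parameters of the reduced courtship assay: a
#' circular arena with a wingless female fixed at a known position, filmed
#' from above against a bright backlit background.
#'
#' @slot diameter arena diameter in mm.
#' @slot height arena height in mm (not used by the 2D analysis, kept for
#'   provenance).
#' @slot femalePosition numeric length-2, female centroid in mm (arena
#'   center is the origin).
#' @slot femaleBodyLength,maleBodyLength body lengths in mm used by the
#'   renderer and by contact-distance defaults.
#' @slot anteriorDirection angle (rad) of the female's anterior direction
#'   in image coordinates; supplied by annotation, random across trials.
#' @slot pixelScale pixels per mm for rendering/tracking.
#' @slot frameRate frames per second.
#' @slot trialDuration trial length in seconds.
#' @export
setClass("ArenaConfig", representation(
  diameter = "numeric", height = "numeric",
  femalePosition = "numeric", femaleBodyLength = "numeric",
  maleBodyLength = "numeric", anteriorDirection = "numeric",
  pixelScale = "numeric", frameRate = "numeric", trialDuration = "numeric"))

setValidity("ArenaConfig", function(object) {
  msg <- character()
  if (object@diameter <= 0) msg <- c(msg, "diameter must be > 0")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (object@trialDuration <= 0) msg <- c(msg, "trialDuration must be > 0")
  if (length(object@femalePosition) != 2)
    msg <- c(msg, "femalePosition must have length 2")
  else {
    # female body must lie fully inside the arena
    reach <- sqrt(sum(object@femalePosition^2)) + object@femaleBodyLength / 2
    if (reach > object@diameter / 2)
      msg <- c(msg, "female is not fully inside the arena")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ArenaConfig
#'
#' Defaults describe the assay: a 23 mm x 6 mm circular arena, a 2.5 mm
#' female fixed at the center, 24 fps video for a 600 s trial.
#'
#' @param diameter,height arena size (mm).
#' @param femalePosition female centroid (mm), arena center = origin.
#' @param femaleBodyLength,maleBodyLength body lengths (mm).
#' @param anteriorDirection annotated female anterior direction (rad).
#' @param pixelScale pixels per mm used when rendering.
#' @param frameRate frames per second.
#' @param trialDuration trial duration (s).
#' @return An \linkS4class{ArenaConfig}.
#' @examples
#' arenaConfig(trialDuration = 60)
#' @export
arenaConfig <- function(diameter = 23, height = 6,
                        femalePosition = c(0, 0), femaleBodyLength = 2.5,
                        maleBodyLength = 2.5, anteriorDirection = 0,
                        pixelScale = 10, frameRate = 24,
                        trialDuration = 600) {
  new("ArenaConfig", diameter = diameter, height = height,
      femalePosition = as.numeric(femalePosition),
      femaleBodyLength = femaleBodyLength, maleBodyLength = maleBodyLength,
      anteriorDirection = anteriorDirection, pixelScale = pixelScale,
      frameRate = frameRate, trialDuration = trialDuration)
}

#' Generative scenario for a synthetic courtship experiment
#'
#' Encodes the statistical structure of one experimental condition: the
#' per-behavior angular law around the female (von Mises, or an axial
#' two-component mixture), the asymmetric radial profile of the male's
#' courtship path, behavior occupancies within courtship, and bout/latency
#' time constants. Presets for the packaged experimental conditions are
#' created by \code{\link{wildtypeScenario}} and friends.
#'
#' @slot name scenario label.
#' @slot angularLaws named list (tapping/scissoring/orienting), each a list
#'   with entries \code{type} ("vonmises" or "axial"), \code{mu} (rad) and
#'   \code{kappa} (>= 0; 0 = uniform, Inf = degenerate at mu).
#' @slot occupancies named fractions of courtship time per element plus
#'   "none"; must sum to 1.
#' @slot dAGen,dPGen maximal male-female centroid distance (mm) at the
#'   female's anterior (theta = 0) and posterior (theta = +-pi) poles.
#' @slot flankDip depth (mm) of the radial-profile dip at the female's
#'   flanks (theta = +-pi/2); 0 gives a pure cosine blend.
#' @slot radialNoiseSd stationary sd (mm) of the smooth radial noise.
#' @slot boutMeanS mean behavior-bout duration (s).
#' @slot latencyMeanS mean courtship latency (s, exponential).
#' @slot courtshipBoutMeanS,breakMeanS mean durations (s) of courtship
#'   bouts and of the non-courtship breaks between them.
#' @slot maxSpeed maximum male speed (mm/s) the trajectory respects.
#' @slot transitAngSpeed angular speed (rad/s) used when the male moves
#'   between behavior anchor angles.
#' @slot wingExtRad wing-extension angle (rad) during scissoring.
#' @slot nFlies default cohort size.
#' @slot seed base seed; fly i uses seed + i.
#' @export
setClass("ScenarioConfig", representation(
  name = "character", angularLaws = "list", occupancies = "numeric",
  dAGen = "numeric", dPGen = "numeric", flankDip = "numeric",
  radialNoiseSd = "numeric", boutMeanS = "numeric", latencyMeanS = "numeric",
  courtshipBoutMeanS = "numeric", breakMeanS = "numeric",
  maxSpeed = "numeric", transitAngSpeed = "numeric", wingExtRad = "numeric",
  nFlies = "numeric", seed = "numeric"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  occ <- object@occupancies
  if (!identical(sort(names(occ)), sort(BEHAVIOR_LEVELS)))
    msg <- c(msg, "occupancies must be named tapping/scissoring/orienting/none")
  else {
    if (any(occ < 0)) msg <- c(msg, "occupancies must be nonnegative")
    if (abs(sum(occ) - 1) > 1e-9)
      msg <- c(msg, "occupancies must sum to 1 (within 1e-9)")
  }
  if (!all(COURTSHIP_ELEMENTS %in% names(object@angularLaws)))
    msg <- c(msg, "angularLaws must cover tapping, scissoring and orienting")
  for (b in intersect(COURTSHIP_ELEMENTS, names(object@angularLaws))) {
    law <- object@angularLaws[[b]]
    if (!is.list(law) || is.null(law$kappa) || law$kappa < 0)
      msg <- c(msg, sprintf("angular law for %s needs kappa >= 0", b))
    if (!is.null(law$type) && !law$type %in% c("vonmises", "axial"))
      msg <- c(msg, sprintf("unknown angular law type for %s", b))
  }
  if (object@dAGen <= 0 || object@dPGen <= 0)
    msg <- c(msg, "dAGen and dPGen must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-frame body and wing poses of the two flies
#'
#' The pipeline's central record: one row per frame with the male and
#' female centroid (mm), body orientation (rad, head direction), wing
#' angles (rad, relative to the body axis, 0 = folded), and a gap flag for
#' frames where tracking failed (contact/overlap, segmentation failure).
#' Gap frames carry NA male pose fields and are never silently
#' interpolated; downstream statistics skip them.
#'
#' @slot poses data.frame with columns frame, time_s, male_x_mm, male_y_mm,
#'   male_orientation_rad, male_wing_l_rad, male_wing_r_rad, female_x_mm,
#'   female_y_mm, female_orientation_rad, gap.
#' @slot frameRate frames per second.
#' @slot pixelScale pixels per mm (NA when the trial was not rendered).
#' @slot anteriorDirection annotated female anterior direction (rad).
#' @export
setClass("TrackedTrial", representation(
  poses = "data.frame", frameRate = "numeric", pixelScale = "numeric",
  anteriorDirection = "numeric"))

TRIAL_COLS <- c("frame", "time_s", "male_x_mm", "male_y_mm",
                "male_orientation_rad", "male_wing_l_rad", "male_wing_r_rad",
                "female_x_mm", "female_y_mm", "female_orientation_rad", "gap")

setValidity("TrackedTrial", function(object) {
  msg <- character()
  if (!all(TRIAL_COLS %in% names(object@poses)))
    msg <- c(msg, paste("poses must have columns:", paste(TRIAL_COLS, collapse = ", ")))
  else if (nrow(object@poses) > 1) {
    ok <- !object@poses$gap
    if (any(ok)) {
      fx <- object@poses$female_x_mm[ok]; fy <- object@poses$female_y_mm[ok]
      if (stats::sd(fx) > 0.5 || stats::sd(fy) > 0.5)
        msg <- c(msg, "female centroid is not stationary (assay violated)")
    }
    if (any(diff(object@poses$frame) != 1))
      msg <- c(msg, "frames must be consecutive (gap frames stay as rows)")
  }
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-frame behavior labels after hierarchy and bout masking
#'
#' Mutually exclusive per-frame element labels. Exactly one label per
#' frame; any label other than "none" lies inside an annotated courtship
#' bout. Bout intervals are half-open \code{[start_frame, end_frame)} in
#' 0-based frame indices, non-overlapping and sorted.
#'
#' @slot label factor with levels tapping, scissoring, orienting, none.
#' @slot scores numeric matrix (nframes x 3) of raw per-behavior margins
#'   (may have zero rows when labels are ground truth).
#' @slot inBout logical, courtship-bout membership per frame.
#' @slot bouts data.frame(start_frame, end_frame), half-open, 0-based.
#' @export
setClass("BehaviorLabels", representation(
  label = "factor", scores = "matrix", inBout = "logical",
  bouts = "data.frame"))

setValidity("BehaviorLabels", function(object) {
  msg <- character()
  if (!identical(levels(object@label), BEHAVIOR_LEVELS))
    msg <- c(msg, "label levels must be tapping, scissoring, orienting, none")
  if (length(object@label) != length(object@inBout))
    msg <- c(msg, "label and inBout lengths differ")
  if (any(is.na(object@label)))
    msg <- c(msg, "every frame must carry exactly one label")
  if (any(object@label != "none" & !object@inBout))
    msg <- c(msg, "non-none labels outside courtship bouts")
  b <- object@bouts
  if (nrow(b)) {
    if (any(b$end_frame <= b$start_frame))
      msg <- c(msg, "bouts must be non-empty half-open intervals")
    if (is.unsorted(b$start_frame, strictly = TRUE) ||
        any(b$start_frame[-1] < b$end_frame[-nrow(b)]))
      msg <- c(msg, "bouts must be sorted and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' A synthetic trial: tracked poses plus ground truth
#'
#' @slot trial the \linkS4class{TrackedTrial}.
#' @slot labels ground-truth \linkS4class{BehaviorLabels}.
#' @slot scenario the generating \linkS4class{ScenarioConfig}.
#' @slot flySeed the per-fly seed used.
#' @export
setClass("SyntheticTrial", representation(
  trial = "TrackedTrial", labels = "BehaviorLabels",
  scenario = "ScenarioConfig", flySeed = "numeric"))

setValidity("SyntheticTrial", function(object) {
  if (nrow(object@trial@poses) != length(object@labels@label))
    "frame count of poses and labels differ" else TRUE
})

#' Female-centered polar track
#'
#' Per-frame male angular position theta (rad; female anterior = 0, range
#' (-pi, pi]) and male-female centroid distance r (mm), with the courtship
#' mask, per-frame labels, instantaneous speed, and the copulation-attempt
#' removal mask.
#'
#' @slot data data.frame with columns frame, time_s, theta_rad, r_mm,
#'   speed_mm_s, courtship, label, removed, gap.
#' @slot frameRate frames per second.
#' @export
setClass("PolarTrack", representation(data = "data.frame",
                                      frameRate = "numeric"))

setValidity("PolarTrack", function(object) {
  need <- c("frame", "time_s", "theta_rad", "r_mm", "speed_mm_s",
            "courtship", "label", "removed", "gap")
  msg <- character()
  if (!all(need %in% names(object@data)))
    msg <- c(msg, paste("data must have columns:", paste(need, collapse = ", ")))
  else {
    th <- object@data$theta_rad; r <- object@data$r_mm
    if (any(th <= -pi - 1e-12 | th > pi + 1e-12, na.rm = TRUE))
      msg <- c(msg, "theta_rad must lie in (-pi, pi]")
    if (any(r < 0, na.rm = TRUE)) msg <- c(msg, "r_mm must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' 50-bin courtship path profile
#'
#' Mean male-female centroid distance per angular bin over courtship
#' frames, with per-bin frame counts and the anterior/posterior maxima
#' D_A and D_P. Bins are 50 equal half-open intervals partitioning
#' (-pi, pi]; empty bins carry NA means and are excluded from the maxima.
#'
#' @slot binCenter bin centers (rad), length 50.
#' @slot meanR per-bin mean distance (mm), NA where unoccupied.
#' @slot counts per-bin frame counts.
#' @slot dA,dP maxima of the bin means over the anterior
#'   (bin center strictly inside (-pi/2, pi/2)) and posterior halves;
#'   NA when a half has no occupied bin.
#' @export
setClass("PathProfile", representation(
  binCenter = "numeric", meanR = "numeric", counts = "numeric",
  dA = "numeric", dP = "numeric"))

setValidity("PathProfile", function(object) {
  msg <- character()
  if (length(object@binCenter) != 50 || length(object@meanR) != 50 ||
      length(object@counts) != 50)
    msg <- c(msg, "profile must have exactly 50 bins")
  if (!is.na(object@dA) && object@dA <= 0) msg <- c(msg, "dA must be > 0")
  if (!is.na(object@dP) && object@dP <= 0) msg <- c(msg, "dP must be > 0")
  if (length(msg)) msg else TRUE
})

#' Circular summary of an angular sample
#'
#' Mean direction, Rayleigh resultant length R, sample size, the unimodal
#' Rayleigh p-value, the axial (angle-doubled) p-value when the gated
#' bimodality stage ran, and the modality verdict.
#'
#' @slot meanAngle mean direction (rad); for an axial-bimodal verdict this
#'   is the detected axis (in (-pi/2, pi/2]).
#' @slot R resultant length in [0, 1] (of the raw angles; for the axial
#'   stage the doubled-angle resultant is in \code{RAxial}).
#' @slot RAxial resultant length of the doubled angles (NA if not run).
#' @slot n sample size.
#' @slot pUnimodal unimodal Rayleigh p-value.
#' @slot pAxial axial-stage p-value; NA whenever the gate stopped the
#'   axial stage (i.e. the unimodal test was already significant).
#' @slot verdict one of "unimodal", "axial-bimodal", "uniform", or "" when
#'   only a plain Rayleigh test was run.
#' @slot alpha significance level used by the gate (NA for plain tests).
#' @export
setClass("CircularSummary", representation(
  meanAngle = "numeric", R = "numeric", RAxial = "numeric", n = "numeric",
  pUnimodal = "numeric", pAxial = "numeric", verdict = "character",
  alpha = "numeric"))

setValidity("CircularSummary", function(object) {
  msg <- character()
  if (!is.na(object@R) && (object@R < -1e-12 || object@R > 1 + 1e-12))
    msg <- c(msg, "R must lie in [0, 1]")
  for (p in c(object@pUnimodal, object@pAxial))
    if (!is.na(p) && (p < 0 || p > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ArenaConfig", function(object) {
  cat(sprintf("ArenaConfig: %g mm arena, female at (%g, %g) mm, anterior %g rad\n",
              object@diameter, object@femalePosition[1],
              object@femalePosition[2], object@anteriorDirection))
  cat(sprintf("  %g fps, %g s trial, %g px/mm\n", object@frameRate,
              object@trialDuration, object@pixelScale))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig '%s': n = %d flies, seed %d\n", object@name,
              as.integer(object@nFlies), as.integer(object@seed)))
  occ <- object@occupancies
  cat(sprintf("  occupancies: %s\n",
              paste(sprintf("%s %.2f", names(occ), occ), collapse = ", ")))
  cat(sprintf("  radial profile: D_A %g mm, D_P %g mm, flank dip %g mm\n",
              object@dAGen, object@dPGen, object@flankDip))
})

setMethod("show", "TrackedTrial", function(object) {
  n <- nrow(object@poses)
  cat(sprintf("TrackedTrial: %d frames @ %g fps (%.1f s), %d gap frames\n",
              n, object@frameRate, n / object@frameRate,
              sum(object@poses$gap)))
})

setMethod("show", "BehaviorLabels", function(object) {
  tab <- table(object@label)
  cat(sprintf("BehaviorLabels: %d frames, %d courtship bouts\n",
              length(object@label), nrow(object@bouts)))
  cat("  ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "SyntheticTrial", function(object) {
  cat(sprintf("SyntheticTrial (scenario '%s', fly seed %d)\n",
              object@scenario@name, as.integer(object@flySeed)))
  show(object@trial); show(object@labels)
})

setMethod("show", "PolarTrack", function(object) {
  d <- object@data
  cat(sprintf("PolarTrack: %d frames, %d courtship, %d removed, %d gap\n",
              nrow(d), sum(d$courtship), sum(d$removed), sum(d$gap)))
})

setMethod("show", "PathProfile", function(object) {
  cat(sprintf("PathProfile: %d/50 occupied bins, D_A = %.2f mm, D_P = %.2f mm\n",
              sum(object@counts > 0), object@dA, object@dP))
})

setMethod("show", "CircularSummary", function(object) {
  cat(sprintf("CircularSummary: n = %d, mean %.3f rad, R = %.3f\n",
              as.integer(object@n), object@meanAngle, object@R))
  cat(sprintf("  p_unimodal = %.4g, p_axial = %s, verdict: %s\n",
              object@pUnimodal,
              if (is.na(object@pAxial)) "not run" else sprintf("%.4g", object@pAxial),
              if (nzchar(object@verdict)) object@verdict else "(plain test)"))
})
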