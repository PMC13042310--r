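#' Construct a ScenarioConfig
#'
#' See \linkS4class{ScenarioConfig} for the meaning of every field. The
#' preset constructors (\code{\link{wildtypeScenario}} and friends) are the
#' usual entry points; this constructor exists for custom conditions.
#'
#' @param name scenario label.
#' @param angularLaws named list of per-behavior angular laws; each a list
#'   with \code{type} ("vonmises" or "axial"), \code{mu}, \code{kappa}.
#' @param occupancies named fractions (tapping/scissoring/orienting/none)
#'   of courtship time; must sum to 1 within 1e-9.
#' @param dAGen,dPGen anterior/posterior maximal distances (mm).
#' @param flankDip radial-profile dip at the flanks (mm).
#' @param radialNoiseSd stationary sd of the smooth radial noise (mm).
#' @param boutMeanS mean behavior-bout duration (s).
#' @param latencyMeanS mean courtship latency (s).
#' @param courtshipBoutMeanS,breakMeanS courtship bout / break means (s).
#' @param maxSpeed male speed bound (mm/s).
#' @param transitAngSpeed angular speed between behavior anchors (rad/s).
#' @param wingExtRad scissoring wing-extension angle (rad).
#' @param nFlies cohort size.
#' @param seed base seed (fly i uses seed + i).
#' @return a validated \linkS4class{ScenarioConfig}.
#' @export
scenarioConfig <- function(name = "custom",
                           angularLaws = list(
                             tapping    = list(type = "vonmises", mu = pi, kappa = 4),
                             scissoring = list(type = "vonmises", mu = 0,  kappa = 2.5),
                             orienting  = list(type = "vonmises", mu = 0,  kappa = 2)),
                           occupancies = c(tapping = 0.40, scissoring = 0.30,
                                           orienting = 0.20, none = 0.10),
                           dAGen = 5.7, dPGen = 3.8, flankDip = 1.5,
                           radialNoiseSd = 0.3, boutMeanS = 2,
                           latencyMeanS = 30, courtshipBoutMeanS = 120,
                           breakMeanS = 30, maxSpeed = 35,
                           transitAngSpeed = 6, wingExtRad = pi / 3,
                           nFlies = 62, seed = 42) {
  occupancies <- unlist(occupancies)
  if (abs(sum(occupancies) - 1) > 1e-9)
    stop("occupancies must sum to 1 (within 1e-9), got ", sum(occupancies))
  new("ScenarioConfig", name = name, angularLaws = angularLaws,
      occupancies = occupancies[BEHAVIOR_LEVELS], dAGen = dAGen, dPGen = dPGen,
      flankDip = flankDip, radialNoiseSd = radialNoiseSd, boutMeanS = boutMeanS,
      latencyMeanS = latencyMeanS, courtshipBoutMeanS = courtshipBoutMeanS,
      breakMeanS = breakMeanS, maxSpeed = maxSpeed,
      transitAngSpeed = transitAngSpeed, wingExtRad = wingExtRad,
      nFlies = nFlies, seed = seed)
}

#' Packaged experimental-condition presets
#'
#' Each preset encodes one experimental manipulation purely as generative
#' parameters (angular laws, radial asymmetry, occupancies); nothing about
#' the optics or surgery is simulated.
#'
#' \describe{
#'   \item{wildtype}{Intact vision, intact female. Tapping concentrated at
#'     the female's posterior (von Mises mu = pi), orienting and scissoring
#'     at her anterior (mu = 0); anterior-biased radial profile with
#'     maximal distances 5.7 mm (anterior) and 3.8 mm (posterior), so the
#'     generative D_A/D_P asymmetry is 1.5. The three elements occupy 90\%
#'     of courtship time.}
#'   \item{redLight}{Limited vision. Tapping and scissoring become axial
#'     mixtures along the anterior-posterior axis, orienting moves to the
#'     posterior, the radial asymmetry flips below 1, courtship is
#'     shorter, and tapping occupancy rises at scissoring's expense.}
#'   \item{headless}{Decapitated female: symmetric radial profile,
#'     tapping axial along the body axis, orienting/scissoring uniform,
#'     less scissoring.}
#'   \item{headPosterior}{Head transplanted to the posterior end: radial
#'     asymmetry flipped, tapping at the anterior, orienting/scissoring
#'     uniform.}
#'   \item{whiteEyed}{White-eyed female: reduced anterior distance,
#'     tapping still posterior, orienting/scissoring axial, less
#'     scissoring.}
#' }
#'
#' @param nFlies cohort size (default 62, the wildtype cohort size).
#' @param seed base seed.
#' @return a \linkS4class{ScenarioConfig}.
#' @examples
#' wildtypeScenario(nFlies = 4)
#' @export
wildtypeScenario <- function(nFlies = 62, seed = 42)
  scenarioConfig(name = "wildtype", nFlies = nFlies, seed = seed)

#' @rdname wildtypeScenario
#' @export
redLightScenario <- function(nFlies = 32, seed = 42)
  scenarioConfig(
    name = "redLight",
    angularLaws = list(
      tapping    = list(type = "axial",    mu = pi, kappa = 4),
      scissoring = list(type = "axial",    mu = 0,  kappa = 3),
      orienting  = list(type = "vonmises", mu = pi, kappa = 2)),
    occupancies = c(tapping = 0.50, scissoring = 0.18, orienting = 0.20,
                    none = 0.12),
    dAGen = 3.4, dPGen = 3.8, courtshipBoutMeanS = 60, breakMeanS = 60,
    nFlies = nFlies, seed = seed)

#' @rdname wildtypeScenario
#' @export
headlessScenario <- function(nFlies = 32, seed = 42)
  scenarioConfig(
    name = "headless",
    angularLaws = list(
      tapping    = list(type = "axial",    mu = pi, kappa = 3),
      scissoring = list(type = "vonmises", mu = 0,  kappa = 0),
      orienting  = list(type = "vonmises", mu = 0,  kappa = 0)),
    occupancies = c(tapping = 0.45, scissoring = 0.20, orienting = 0.25,
                    none = 0.10),
    dAGen = 4.5, dPGen = 4.5, nFlies = nFlies, seed = seed)

#' @rdname wildtypeScenario
#' @export
headPosteriorScenario <- function(nFlies = 63, seed = 42)
  scenarioConfig(
    name = "headPosterior",
    angularLaws = list(
      tapping    = list(type = "vonmises", mu = 0, kappa = 4),
      scissoring = list(type = "vonmises", mu = 0, kappa = 0),
      orienting  = list(type = "vonmises", mu = 0, kappa = 0)),
    dAGen = 3.8, dPGen = 5.7, nFlies = nFlies, seed = seed)

#' @rdname wildtypeScenario
#' @export
whiteEyedScenario <- function(nFlies = 48, seed = 42)
  scenarioConfig(
    name = "whiteEyed",
    angularLaws = list(
      tapping    = list(type = "vonmises", mu = pi, kappa = 4),
      scissoring = list(type = "axial",    mu = 0,  kappa = 3),
      orienting  = list(type = "axial",    mu = 0,  kappa = 3)),
    occupancies = c(tapping = 0.42, scissoring = 0.22, orienting = 0.26,
                    none = 0.10),
    dAGen = 4.8, dPGen = 3.8, nFlies = nFlies, seed = seed)

#' Radial profile of the courtship path
#'
#' Expected male-female centroid distance as a function of the male's
#' angular position theta around the female: a cosine blend between the
#' anterior maximum \code{dAGen} at theta = 0 and the posterior maximum
#' \code{dPGen} at theta = +-pi, minus a flank dip proportional to
#' sin^2(theta). With \code{flankDip = 0} this reduces to the pure
#' single-lobed blend D_P + (D_A - D_P)(1 + cos theta)/2; with a dip
#' deeper than |D_A - D_P|/2 the profile has local maxima at both poles,
#' matching the peanut-shaped Cartesian courtship path of real males
#' (closest at the flanks, locally farthest at head and abdomen tip).
#'
#' @param theta angles (rad).
#' @param scenario a \linkS4class{ScenarioConfig}.
#' @return distances (mm).
#' @export
radialProfile <- function(theta, scenario) {
  scenario@dPGen + (scenario@dAGen - scenario@dPGen) * (1 + cos(theta)) / 2 -
    scenario@flankDip * sin(theta)^2
}
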