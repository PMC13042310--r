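#' Transform a trial into female-centered polar coordinates
#'
#' theta is the male's angular position measured from the annotated female
#' anterior direction, wrapped to (-pi, pi]; r is the male-female centroid
#' distance. The per-frame courtship mask comes from the supplied labels'
#' bout membership, and per-frame element labels ride along for the
#' angular-location statistics. Instantaneous speed uses central finite
#' differences (one-sided at the ends); gap frames propagate NA.
#'
#' @param trial a \linkS4class{TrackedTrial}.
#' @param labels a \linkS4class{BehaviorLabels} for the same trial; when
#'   omitted, every frame counts as courtship and is labeled none.
#' @return a \linkS4class{PolarTrack}.
#' @export
toPolar <- function(trial, labels = NULL) {
  if (is.na(trial@anteriorDirection))
    stop("female anterior_direction annotation is missing")
  p <- trial@poses
  n <- nrow(p)
  dx <- p$male_x_mm - p$female_x_mm
  dy <- p$male_y_mm - p$female_y_mm
  theta <- wrapAngle(atan2(dy, dx) - trial@anteriorDirection)
  r <- sqrt(dx^2 + dy^2)
  fps <- trial@frameRate
  vx <- centralDiff(p$male_x_mm) * fps
  vy <- centralDiff(p$male_y_mm) * fps
  speed <- sqrt(vx^2 + vy^2)
  if (is.null(labels)) {
    court <- rep(TRUE, n)
    lab <- factor(rep("none", n), levels = BEHAVIOR_LEVELS)
  } else {
    if (length(labels@label) != n) stop("labels do not match the trial length")
    court <- labels@inBout
    lab <- labels@label
  }
  gap <- p$gap
  theta[gap] <- NA; r[gap] <- NA; speed[gap] <- NA
  new("PolarTrack",
      data = data.frame(frame = p$frame, time_s = p$time_s,
                        theta_rad = theta, r_mm = r, speed_mm_s = speed,
                        courtship = court, label = lab,
                        removed = FALSE, gap = gap),
      frameRate = fps)
}

# central finite difference, one-sided at the ends; NA-safe around gaps
centralDiff <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

#' Mask long low-motion contact runs (copulation attempts)
#'
#' Males attempting to copulate with the fixed female sit nearly still in
#' contact with her for long stretches; those runs distort the courtship
#' path and are removed from all downstream statistics. A frame belongs to
#' a run when its speed is below \code{maxSpeed} and its centroid distance
#' below \code{contactR}; contiguous runs lasting at least
#' \code{minDurationS} get their \code{removed} flag set.
#'
#' @param track a \linkS4class{PolarTrack}.
#' @param minDurationS minimum run duration (s), default 30.
#' @param maxSpeed speed threshold (mm/s), default 0.5.
#' @param contactR centroid contact distance (mm), default 2.8 (half body
#'   lengths of the two flies plus a small reach).
#' @return the track with updated \code{removed} flags.
#' @export
removeCopulationAttempts <- function(track, minDurationS = 30,
                                     maxSpeed = 0.5, contactR = 2.8) {
  stopifnot(minDurationS > 0, maxSpeed > 0)
  d <- track@data
  cand <- !is.na(d$speed_mm_s) & !is.na(d$r_mm) &
    d$speed_mm_s < maxSpeed & d$r_mm < contactR
  runs <- rle(cand)
  minLen <- round(minDurationS * track@frameRate)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (i in seq_along(runs$lengths))
    if (runs$values[i] && runs$lengths[i] >= minLen)
      d$removed[starts[i]:ends[i]] <- TRUE
  track@data <- d
  track
}

# frames that enter spatial statistics
analysisFrames <- function(d) d$courtship & !d$removed & !d$gap & !is.na(d$theta_rad)

# half-open 50-bin index over (-pi, pi]
binIndex <- function(theta, nbins = 50) {
  w <- 2 * pi / nbins
  i <- ceiling((theta + pi) / w)
  pmin(pmax(i, 1L), nbins)
}

#' 50-bin courtship path
#'
#' Mean male-female centroid distance per angular bin over courtship
#' frames (copulation-attempt and gap frames excluded). Bins are 50 equal
#' half-open intervals partitioning (-pi, pi]; unoccupied bins carry NA
#' means and never enter the D_A/D_P maxima.
#'
#' @param track a \linkS4class{PolarTrack}.
#' @return a \linkS4class{PathProfile}.
#' @export
courtshipPath <- function(track) {
  d <- track@data
  keep <- analysisFrames(d)
  if (!any(keep)) stop("no courtship frames; courtship path undefined")
  nbins <- 50L
  idx <- binIndex(d$theta_rad[keep], nbins)
  r <- d$r_mm[keep]
  counts <- tabulate(idx, nbins)
  sums <- as.numeric(rowsum(r, idx, reorder = TRUE))
  meanR <- rep(NA_real_, nbins)
  meanR[sort(unique(idx))] <- sums / counts[counts > 0]
  w <- 2 * pi / nbins
  centers <- -pi + (seq_len(nbins) - 0.5) * w
  prof <- new("PathProfile", binCenter = centers, meanR = meanR,
              counts = as.numeric(counts), dA = NA_real_, dP = NA_real_)
  ant <- anteriorBins(centers)
  occA <- ant & counts > 0
  occP <- !ant & counts > 0
  prof@dA <- if (any(occA)) max(meanR[occA]) else NA_real_
  prof@dP <- if (any(occP)) max(meanR[occP]) else NA_real_
  prof
}

# anterior half by bin center: strictly -pi/2 < center < pi/2 (bins whose
# center sits exactly on +-pi/2 count as posterior, per the strict
# inequalities in the ratio's definition)
anteriorBins <- function(centers) centers > -pi / 2 + 1e-12 &
  centers < pi / 2 - 1e-12

#' Anterior-to-posterior maximum distance ratio (D_A/D_P)
#'
#' Ratio of the maximum courtship-path bin mean when the male is on the
#' female's front half (-pi/2 < theta < pi/2) to the maximum on her rear
#' half. Halves are assigned by bin center.
#'
#' @param profile a \linkS4class{PathProfile}.
#' @return the ratio; NA with a warning when either half has no occupied
#'   bin.
#' @export
dadpRatio <- function(profile) {
  if (is.na(profile@dA) || is.na(profile@dP)) {
    warning("D_A/D_P undefined: one angular half has no occupied bin")
    return(NA_real_)
  }
  profile@dA / profile@dP
}

#' Angular location of a courtship element for one fly
#'
#' Circular mean and resultant length of the male's angular position over
#' all frames carrying a positive classification of the element (within
#' courtship, after copulation-attempt removal).
#'
#' @param track a \linkS4class{PolarTrack}.
#' @param element one of "tapping", "scissoring", "orienting".
#' @return list(meanAngle, R, n); meanAngle and R are NA with n = 0 when
#'   the fly has no such frames (the fly is then excluded from population
#'   statistics).
#' @export
behaviorLocation <- function(track, element) {
  element <- match.arg(element, COURTSHIP_ELEMENTS)
  d <- track@data
  keep <- analysisFrames(d) & d$label == element
  if (!any(keep))
    return(list(meanAngle = NA_real_, R = NA_real_, n = 0L))
  th <- d$theta_rad[keep]
  list(meanAngle = circMean(th), R = circR(th), n = length(th))
}

#' Population-level circular summary of per-fly mean angles
#'
#' Mean angle and resultant length over per-fly mean locations
#' (unweighted; per-fly durations scale plot point sizes only), with the
#' gated bimodal Rayleigh test applied at the population level. The
#' returned arrow geometry matches the circular-plot convention: arrow
#' direction = population mean angle, arrow length = population R.
#'
#' @param perFlyMeans per-fly mean angles (rad); NAs dropped.
#' @param perFlyDurations per-fly element durations (s), same length.
#' @param alpha significance level for the gated test.
#' @return list(summary = \linkS4class{CircularSummary},
#'   arrow = list(angle, length), pointSize = durations scaled to [0, 1]).
#' @export
populationSummary <- function(perFlyMeans, perFlyDurations = NULL,
                              alpha = 0.05) {
  ok <- !is.na(perFlyMeans)
  m <- perFlyMeans[ok]
  if (length(m) < 3)
    stop("population summary needs at least 3 flies with defined means")
  cs <- bimodalRayleighTest(m, alpha = alpha)
  sizes <- NULL
  if (!is.null(perFlyDurations)) {
    dd <- perFlyDurations[ok]
    sizes <- if (max(dd) > 0) dd / max(dd) else rep(0, length(dd))
  }
  list(summary = cs,
       arrow = list(angle = circMean(m), length = circR(m)),
       pointSize = sizes)
}

#' Per-fly spatial summary
#'
#' Convenience wrapper running the whole spatial stage for one fly:
#' polar transform, copulation-attempt removal, courtship path, D_A/D_P,
#' and per-element angular locations.
#'
#' @param trial a \linkS4class{TrackedTrial}.
#' @param labels a \linkS4class{BehaviorLabels}.
#' @param ... passed to \code{\link{removeCopulationAttempts}}.
#' @return list(track, profile, dadp, locations) where locations is a
#'   named list over elements.
#' @export
spatialSummary <- function(trial, labels, ...) {
  track <- removeCopulationAttempts(toPolar(trial, labels), ...)
  prof <- courtshipPath(track)
  locs <- lapply(stats::setNames(nm = COURTSHIP_ELEMENTS),
                 function(b) behaviorLocation(track, b))
  list(track = track, profile = prof,
       dadp = suppressWarnings(dadpRatio(prof)), locations = locs)
}
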