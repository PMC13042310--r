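#' Courtship latency
#'
#' Time (s) from trial start to the first frame of the first annotated
#' courtship bout. NA when the male never courts.
#'
#' @param labels a \linkS4class{BehaviorLabels}.
#' @param frameRate frames per second.
#' @return latency in seconds.
#' @export
latency <- function(labels, frameRate) {
  if (!nrow(labels@bouts)) return(NA_real_)
  labels@bouts$start_frame[1] / frameRate
}

#' Courtship index and per-element indices
#'
#' The courtship index is the fraction of the trial the male spent
#' courting, t_courting / t_trial. Each element index is the fraction of
#' total courtship time spent in that element, t_element / t_total
#' (normalized by courtship time, not trial time), so the three element
#' indices plus the none-within-courtship fraction sum to 1.
#'
#' @param labels a \linkS4class{BehaviorLabels}.
#' @param frameRate frames per second.
#' @return data.frame with latency_s, courtship_index, tapping_index,
#'   scissoring_index, orienting_index, none_index.
#' @export
temporalIndices <- function(labels, frameRate) {
  stopifnot(frameRate > 0)
  n <- length(labels@label)
  tc <- sum(labels@inBout)
  ci <- tc / n
  el <- if (tc > 0)
    vapply(BEHAVIOR_LEVELS, function(b)
      sum(labels@label == b & labels@inBout) / tc, numeric(1))
  else stats::setNames(rep(NA_real_, 4), BEHAVIOR_LEVELS)
  data.frame(latency_s = latency(labels, frameRate), courtship_index = ci,
             tapping_index = el[["tapping"]],
             scissoring_index = el[["scissoring"]],
             orienting_index = el[["orienting"]],
             none_index = el[["none"]])
}

#' Sideways-velocity profile around the female
#'
#' The sideways speed of the male is the magnitude of the component of his
#' centroid velocity perpendicular to the male-to-female vector; in the
#' female-centered polar frame this is r * |dtheta/dt|. Speeds are
#' averaged per angular bin (the same 50 bins as the courtship path) over
#' courtship frames, and summarized over three sectors: anterior V_A
#' (|theta| < pi/4), posterior V_P (|theta| > 3pi/4) and medio-lateral
#' V_ML (the rest). Sector summaries are unweighted means of the occupied
#' bin means.
#'
#' @param track a \linkS4class{PolarTrack}.
#' @param sectorHalfWidth half-width (rad) of the anterior/posterior
#'   sectors, default pi/4.
#' @return list(binCenter, meanSideways, counts, vA, vP, vML).
#' @export
velocityProfile <- function(track, sectorHalfWidth = pi / 4) {
  d <- track@data
  fps <- track@frameRate
  if (sum(!d$gap) < 2) stop("velocity profile needs >= 2 non-gap frames")
  dth <- wrapAngle(centralDiffAngle(d$theta_rad))
  side <- abs(d$r_mm * dth * fps)
  keep <- analysisFrames(d) & !is.na(side)
  nbins <- 50L
  idx <- binIndex(d$theta_rad[keep], nbins)
  counts <- tabulate(idx, nbins)
  sums <- rep(0, nbins)
  if (any(keep))
    sums[sort(unique(idx))] <- as.numeric(rowsum(side[keep], idx, reorder = TRUE))
  meanS <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  w <- 2 * pi / nbins
  centers <- -pi + (seq_len(nbins) - 0.5) * w
  inA <- abs(centers) < sectorHalfWidth
  inP <- abs(centers) > pi - sectorHalfWidth
  inML <- !inA & !inP
  secMean <- function(m) {
    v <- meanS[m & counts > 0]
    if (length(v)) mean(v) else NA_real_
  }
  list(binCenter = centers, meanSideways = meanS, counts = as.numeric(counts),
       vA = secMean(inA), vP = secMean(inP), vML = secMean(inML))
}

# central difference on a circular series (wrap-aware), one-sided ends
centralDiffAngle <- function(th) {
  n <- length(th)
  if (n < 2) return(rep(NA_real_, n))
  d <- numeric(n)
  d[2:(n - 1)] <- wrapAngle(th[3:n] - th[1:(n - 2)]) / 2
  d[1] <- wrapAngle(th[2] - th[1])
  d[n] <- wrapAngle(th[n] - th[n - 1])
  d
}
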