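#' Segment flies in a backlit frame
#'
#' Dark-on-bright segmentation by background subtraction: pixels where
#' \code{background - frame > threshold} form the foreground, connected
#' components below \code{minAreaPx} are discarded. Any number of
#' components other than two is not an error here; the caller flags such
#' frames as gaps.
#'
#' @param frame,background grayscale matrices of identical shape
#'   (gray levels 0-255).
#' @param threshold gray-level difference threshold (default 60).
#' @param minAreaPx minimum component area in pixels.
#' @return list of components, each a list(px, py) of 1-based pixel
#'   (column, row) indices; the list carries attribute \code{labels}, the
#'   labeled image.
#' @export
segmentFlies <- function(frame, background, threshold = 60,
                         minAreaPx = 30) {
  if (!all(dim(frame) == dim(background)))
    stop("frame and background must have the same shape")
  mask <- (background - frame) > threshold
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  comps <- list()
  if (nlab > 0) {
    areas <- tabulate(lab[lab > 0], nlab)
    for (l in which(areas >= minAreaPx)) {
      idx <- which(lab == l, arr.ind = TRUE)
      comps[[length(comps) + 1L]] <- list(px = idx[, 2], py = idx[, 1])
    }
  }
  attr(comps, "labels") <- lab
  comps
}

#' Fit a fly pose to one connected component
#'
#' The body is isolated by a morphological opening that erases the thin
#' wings; its centroid and orientation come from the first and second
#' central moments of the opened pixels (the ellipse axes are 4 sigma
#' along the principal directions, matching a filled ellipse). Wing
#' pixels are the component's pixels left outside the (slightly inflated)
#' fitted body ellipse; their side follows the sign of their lateral
#' body-frame coordinate, and each side's wing angle is the median angle
#' between the hinge-to-pixel direction and the tail direction over the
#' side's outer pixels. The body axis leaves a head-tail ambiguity of pi;
#' the returned \code{headingHint} points away from the wing pixels
#' (wings trail the body) when wings are present.
#'
#' @param comp one component from \code{\link{segmentFlies}}.
#' @param pixelScale pixels per mm.
#' @param minAreaPx minimum component area.
#' @param axisRatioMin below this major/minor axis ratio the orientation
#'   is considered undefined (near-circular blob) and returned NA.
#' @return list(cx, cy, axisAngle, majorMm, minorMm, wingL, wingR,
#'   headingHint, areaPx); cx/cy in continuous px coordinates.
#' @export
fitPose <- function(comp, pixelScale, minAreaPx = 30, axisRatioMin = 1.15) {
  n <- length(comp$px)
  if (n < minAreaPx) stop("component below minimum area")
  # pixel centers in continuous px coordinates
  x <- comp$px - 0.5
  y <- comp$py - 0.5
  # opening via a small sub-image to erase wings
  x0 <- min(comp$px); y0 <- min(comp$py)
  sub <- matrix(0L, max(comp$py) - y0 + 1L, max(comp$px) - x0 + 1L)
  sub[cbind(comp$py - y0 + 1L, comp$px - x0 + 1L)] <- 1L
  brushSize <- 7L
  if (nrow(sub) > brushSize && ncol(sub) > brushSize) {
    op <- EBImage::opening(sub, EBImage::makeBrush(brushSize, "disc"))
    body <- which(op > 0, arr.ind = TRUE)
  } else body <- NULL
  if (is.null(body) || nrow(body) < minAreaPx / 2) {
    bx <- x; by <- y               # opening ate everything: fall back
  } else {
    bx <- body[, 2] + x0 - 1.5     # back to continuous px
    by <- body[, 1] + y0 - 1.5
  }
  cx <- mean(bx); cy <- mean(by)
  cxx <- mean((bx - cx)^2); cyy <- mean((by - cy)^2)
  cxy <- mean((bx - cx) * (by - cy))
  eg <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  major <- 2 * sqrt(max(eg$values[1], 0))
  minor <- 2 * sqrt(max(eg$values[2], 1e-9))
  axisAngle <- if (major / minor < axisRatioMin) NA_real_
               else atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  out <- list(cx = cx, cy = cy, axisAngle = axisAngle,
              majorMm = major / pixelScale, minorMm = minor / pixelScale,
              wingL = 0, wingR = 0, headingHint = NA_real_, areaPx = n)
  if (is.na(axisAngle)) return(out)

  # wing pixels: outside the inflated fitted body ellipse
  ca <- cos(axisAngle); sa <- sin(axisAngle)
  u <- (x - cx) * ca + (y - cy) * sa
  v <- -(x - cx) * sa + (y - cy) * ca
  inflate <- 1.15
  outside <- (u / (major * inflate))^2 + (v / (minor * inflate))^2 > 1
  if (!any(outside)) return(out)
  uo <- u[outside]; vo <- v[outside]
  # wings trail the body: the heading points away from the wing pixels
  tailSign <- sign(sum(uo))
  if (tailSign == 0) tailSign <- 1
  heading <- if (tailSign > 0) wrapAngle(axisAngle + pi) else axisAngle
  out$headingHint <- heading
  # hinge sits behind the body center along the heading
  hingeU <- tailSign * WING_HINGE_FRAC * major
  du <- uo - hingeU; dv <- vo
  tailU <- tailSign                   # unit tail direction in (u, v)
  ang <- acos(pmin(pmax((du * tailU) / sqrt(du^2 + dv^2), -1), 1))
  rr <- sqrt(du^2 + dv^2)
  band <- rr >= 0.6 * max(rr)         # outer pixels define the angle best
  # side by lateral coordinate; left wings have positive v for
  # tailSign < 0 and negative v otherwise (chirality of the body frame)
  leftSide <- if (tailSign > 0) dv < 0 else dv > 0
  wl <- ang[band & leftSide]; wr <- ang[band & !leftSide]
  if (length(wl)) out$wingL <- stats::median(wl)
  if (length(wr)) out$wingR <- stats::median(wr)
  out
}

#' Build a background model from a frame stack
#'
#' Pixelwise median over up to \code{nSample} uniformly spaced frames.
#' The fixed female survives the median but is then simply the static
#' component of every frame.
#'
#' @param stack numeric array [ny, nx, n].
#' @param nSample maximum number of frames used (default 500).
#' @return background matrix.
#' @export
backgroundModel <- function(stack, nSample = 500) {
  n <- dim(stack)[3]
  idx <- unique(round(seq(1, n, length.out = min(nSample, n))))
  apply(stack[, , idx, drop = FALSE], c(1, 2), stats::median)
}

#' Track a rendered or recorded frame stack
#'
#' Full tracking pass: background model, per-frame segmentation and pose
#' fitting, identity resolution (the low-motion track is the fixed
#' female), and male head-tail disambiguation. Deviant frames (fly-fly
#' contact merges the blobs; segmentation failures) become gap frames
#' with NA male pose; gaps are never interpolated.
#'
#' Two segmentation regimes are supported. With an explicit clean
#' \code{background} (empty arena) every frame yields two components;
#' the two continuity-matched tracks are assigned identities by motion
#' (the low-variance track is the fixed female) and it is a hard error
#' when both tracks move. With the default median background model the
#' fixed female is part of the background; she is then segmented once
#' from the background itself and each frame contributes the male
#' component only.
#'
#' Head-tail resolution follows three rules in order: (i) the per-frame
#' axis is made temporally continuous (flip when that reduces the
#' frame-to-frame angular change), which leaves a single global
#' ambiguity; (ii) a majority vote over moving frames aligns the heading
#' with the displacement direction; (iii) when too few frames move, the
#' wing-side prior (wings trail the body) decides.
#'
#' @param stack numeric array [ny, nx, n] of gray frames, or the list
#'   returned by \code{\link{renderTrial}} / \code{\link{readFrames}}.
#' @param arena an \linkS4class{ArenaConfig}; supplies pixelScale,
#'   frameRate and the annotated female anterior direction.
#' @param background optional background matrix (default: median model).
#' @param threshold,minAreaPx passed to \code{\link{segmentFlies}}.
#' @param moveSpeedMin speed (mm/s) above which a frame votes in the
#'   displacement majority.
#' @return a \linkS4class{TrackedTrial}.
#' @export
trackFrames <- function(stack, arena, background = NULL, threshold = 60,
                        minAreaPx = 30, moveSpeedMin = 2) {
  if (is.list(stack)) stack <- stack$frames
  n <- dim(stack)[3]
  if (n < 2) stop("tracking needs at least 2 frames")
  scale <- arena@pixelScale
  if (is.na(scale) || scale <= 0) stop("pixelScale must be set")
  medianBg <- is.null(background)
  if (medianBg) background <- backgroundModel(stack)
  half <- arena@diameter / 2

  femaleFromBg <- NULL
  if (medianBg) {
    # the fixed female persists in the median background; segment her
    # from the background against its own bright level
    flat <- matrix(stats::median(background), nrow(background),
                   ncol(background))
    bcomps <- segmentFlies(background, flat, threshold, minAreaPx)
    if (length(bcomps) != 1)
      stop("background does not contain exactly one static fly; ",
           "the assay requires a fixed female")
    femaleFromBg <- fitPose(bcomps[[1]], scale, minAreaPx)
    expected <- 1L
  } else expected <- 2L

  posesA <- vector("list", n)        # two raw tracks by continuity
  posesB <- vector("list", n)
  gap <- logical(n)
  prevA <- prevB <- NULL
  for (k in seq_len(n)) {
    comps <- segmentFlies(stack[, , k], background, threshold, minAreaPx)
    if (length(comps) != expected) { gap[k] <- TRUE; next }
    f1 <- fitPose(comps[[1]], scale, minAreaPx)
    if (expected == 1L) {
      posesA[[k]] <- f1
      prevA <- f1
      next
    }
    f2 <- fitPose(comps[[2]], scale, minAreaPx)
    if (is.null(prevA)) {
      posesA[[k]] <- f1; posesB[[k]] <- f2
    } else {
      d11 <- (f1$cx - prevA$cx)^2 + (f1$cy - prevA$cy)^2
      d12 <- (f1$cx - prevB$cx)^2 + (f1$cy - prevB$cy)^2
      d21 <- (f2$cx - prevA$cx)^2 + (f2$cy - prevA$cy)^2
      d22 <- (f2$cx - prevB$cx)^2 + (f2$cy - prevB$cy)^2
      if (d11 + d22 <= d12 + d21) {
        posesA[[k]] <- f1; posesB[[k]] <- f2
      } else {
        posesA[[k]] <- f2; posesB[[k]] <- f1
      }
    }
    prevA <- posesA[[k]]; prevB <- posesB[[k]]
  }
  ok <- !gap
  if (sum(ok) < 2) stop("fewer than 2 tracked frames")

  getf <- function(track, f) vapply(track, function(p)
    if (is.null(p)) NA_real_ else p[[f]], numeric(1))

  if (expected == 2L) {
    trackVar <- function(track) {
      cx <- vapply(track[ok], `[[`, numeric(1), "cx")
      cy <- vapply(track[ok], `[[`, numeric(1), "cy")
      stats::var(cx) + stats::var(cy)
    }
    vA <- trackVar(posesA); vB <- trackVar(posesB)
    mobileLimit <- (0.5 * scale)^2     # px^2; ~0.5 mm positional scatter
    if (vA > mobileLimit && vB > mobileLimit)
      stop("both tracks are mobile; the assay requires a fixed female")
    if (vA <= mobileLimit && vB <= mobileLimit) {
      # both static: the assay's female is wingless, so the track with
      # wing evidence (trailing wing pixels) is the male
      hints <- function(track) sum(!is.na(getf(track, "headingHint")))
      if (hints(posesA) <= hints(posesB)) {
        female <- posesA; male <- posesB
      } else { female <- posesB; male <- posesA }
    } else if (vA <= vB) { female <- posesA; male <- posesB }
    else { female <- posesB; male <- posesA }
    fx <- mean(getf(female, "cx"), na.rm = TRUE)
    fy <- mean(getf(female, "cy"), na.rm = TRUE)
  } else {
    male <- posesA
    fx <- femaleFromBg$cx; fy <- femaleFromBg$cy
  }

  mx <- getf(male, "cx"); my <- getf(male, "cy")
  axis <- getf(male, "axisAngle")
  hint <- getf(male, "headingHint")
  wingL <- getf(male, "wingL"); wingR <- getf(male, "wingR")

  heading <- resolveHeading(axis, mx, my, hint, arena@frameRate / scale,
                            moveSpeedMin)
  # wing sides were measured relative to the wing-prior heading; flip
  # them where the resolved heading disagrees with the hint
  flip <- !is.na(hint) & !is.na(heading) &
    abs(wrapAngle(heading - hint)) > pi / 2
  tmp <- wingL[flip]; wingL[flip] <- wingR[flip]; wingR[flip] <- tmp

  px2mm <- function(px) px / scale - half
  poses <- data.frame(
    frame = 0:(n - 1), time_s = (0:(n - 1)) / arena@frameRate,
    male_x_mm = px2mm(mx), male_y_mm = px2mm(my),
    male_orientation_rad = heading,
    male_wing_l_rad = wingL, male_wing_r_rad = wingR,
    female_x_mm = px2mm(fx), female_y_mm = px2mm(fy),
    female_orientation_rad = wrapAngle(arena@anteriorDirection),
    gap = gap | is.na(mx) | is.na(heading))
  new("TrackedTrial", poses = poses, frameRate = arena@frameRate,
      pixelScale = scale, anteriorDirection = arena@anteriorDirection)
}

#' Resolve the male head-tail ambiguity over a trial
#'
#' @param axis per-frame body-axis angles (rad, ambiguous up to pi; NA at
#'   gaps).
#' @param cx,cy per-frame centroids (px).
#' @param hint per-frame wing-prior heading (rad or NA).
#' @param mmPerFramePerPx conversion from px/frame to mm/s.
#' @param moveSpeedMin voting speed threshold (mm/s).
#' @return per-frame heading angles (rad).
#' @export
resolveHeading <- function(axis, cx, cy, hint, mmPerFramePerPx,
                           moveSpeedMin = 2) {
  n <- length(axis)
  h <- axis
  # (i) temporal continuity: flip by pi whenever that reduces the change
  last <- NA_real_
  for (k in seq_len(n)) {
    if (is.na(h[k])) next
    if (!is.na(last) && abs(wrapAngle(h[k] - last)) > pi / 2)
      h[k] <- wrapAngle(h[k] + pi)
    last <- h[k]
  }
  # (ii) global majority vote: align with displacement while moving
  dx <- c(NA, diff(cx)); dy <- c(NA, diff(cy))
  speed <- sqrt(dx^2 + dy^2) * mmPerFramePerPx
  moving <- !is.na(speed) & !is.na(h) & speed > moveSpeedMin
  vote <- sum(cos(h[moving] - atan2(dy[moving], dx[moving])))
  if (sum(moving) >= 10 && abs(vote) > 0.1 * sum(moving)) {
    if (vote < 0) h <- wrapAngle(h + pi)
  } else {
    # (iii) wing-side prior fallback
    okh <- !is.na(hint) & !is.na(h)
    if (any(okh) && sum(cos(h[okh] - hint[okh])) < 0) h <- wrapAngle(h + pi)
  }
  h
}
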