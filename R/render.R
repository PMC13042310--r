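#' Render a synthetic trial as a grayscale frame stack
#'
#' Produces backlit-style frames: dark flies on a uniform bright
#' background. Each fly is a filled body ellipse oriented along its
#' heading; the male's wings are thin segments attached at a hinge behind
#' the body center, drawn at the generated wing angles relative to the
#' negative body axis (the female is wingless in this assay). Optional
#' i.i.d. Gaussian pixel noise can be added.
#'
#' Pixel coordinates are continuous with the origin at the top-left frame
#' corner: \code{px = (mm + diameter/2) * pixelScale}. A pixel (row i,
#' col j) covers the square with center \code{(j - 0.5, i - 0.5)} px;
#' rows advance with y.
#'
#' @param synth a \linkS4class{SyntheticTrial} (or a
#'   \linkS4class{TrackedTrial}).
#' @param arena the \linkS4class{ArenaConfig} (supplies pixelScale and
#'   body sizes).
#' @param frames integer vector of 0-based frame numbers to render;
#'   default all. Length 0 gives an empty stack and an empty truth table.
#' @param noiseSd sd of additive Gaussian pixel noise (gray levels,
#'   default 0 = noise-free).
#' @param bgLevel,flyLevel background and fly gray levels (8-bit).
#' @return list(frames = numeric array [ny, nx, n] of gray levels,
#'   truth = data.frame of per-frame ground truth: centroids (px),
#'   orientations (rad), wing angles (rad) for both flies).
#' @export
renderTrial <- function(synth, arena, frames = NULL, noiseSd = 0,
                        bgLevel = 230, flyLevel = 30) {
  if (is(synth, "SyntheticTrial")) p <- synth@trial@poses else p <- synth@poses
  if (is.na(arena@pixelScale) || arena@pixelScale <= 0)
    stop("pixel_scale must be set to render")
  if (is.null(frames)) frames <- p$frame
  scale <- arena@pixelScale
  npx <- ceiling(arena@diameter * scale)
  n <- length(frames)
  stack <- array(bgLevel, dim = c(npx, npx, n))
  half <- arena@diameter / 2
  aM <- arena@maleBodyLength / 2; bM <- 0.45
  aF <- arena@femaleBodyLength / 2; bF <- 0.5
  na <- rep(NA_real_, n)
  truth <- data.frame(frame = frames,
                      male_cx_px = na, male_cy_px = na,
                      male_orientation_rad = na,
                      male_wing_l_rad = na, male_wing_r_rad = na,
                      female_cx_px = na, female_cy_px = na,
                      female_orientation_rad = na)
  if (n == 0) return(list(frames = stack, truth = truth))
  rows <- match(frames, p$frame)
  if (anyNA(rows)) stop("requested frames not present in the trial")
  for (k in seq_len(n)) {
    i <- rows[k]
    img <- matrix(bgLevel, npx, npx)
    img <- drawFly(img, scale, half,
                   p$female_x_mm[i], p$female_y_mm[i],
                   p$female_orientation_rad[i], aF, bF,
                   wings = NULL, flyLevel = flyLevel)
    img <- drawFly(img, scale, half,
                   p$male_x_mm[i], p$male_y_mm[i],
                   p$male_orientation_rad[i], aM, bM,
                   wings = c(p$male_wing_l_rad[i], p$male_wing_r_rad[i]),
                   flyLevel = flyLevel)
    if (noiseSd > 0)
      img <- pmin(pmax(img + stats::rnorm(length(img), 0, noiseSd), 0), 255)
    stack[, , k] <- img
    truth$male_cx_px[k] <- (p$male_x_mm[i] + half) * scale
    truth$male_cy_px[k] <- (p$male_y_mm[i] + half) * scale
    truth$male_orientation_rad[k] <- p$male_orientation_rad[i]
    truth$male_wing_l_rad[k] <- p$male_wing_l_rad[i]
    truth$male_wing_r_rad[k] <- p$male_wing_r_rad[i]
    truth$female_cx_px[k] <- (p$female_x_mm[i] + half) * scale
    truth$female_cy_px[k] <- (p$female_y_mm[i] + half) * scale
    truth$female_orientation_rad[k] <- p$female_orientation_rad[i]
  }
  list(frames = stack, truth = truth)
}

# wing geometry constants (fractions of the body semi-major axis)
WING_HINGE_FRAC <- 0.3    # hinge distance behind the body center
WING_LEN_FRAC <- 1.2      # wing length
WING_HALFWIDTH_MM <- 0.12

# rasterize one fly (body ellipse + optional wing segments) into img.
# Matrix rows index y, columns x; cell (i, j) has center (j-0.5, i-0.5) px.
drawFly <- function(img, scale, half, x, y, psi, a, b, wings, flyLevel) {
  npx <- nrow(img)
  cx <- (x + half) * scale
  cy <- (y + half) * scale
  reach <- (a * max(1, WING_HINGE_FRAC + WING_LEN_FRAC) + 0.3) * scale
  j0 <- max(1L, floor(cx - reach)); j1 <- min(npx, ceiling(cx + reach))
  i0 <- max(1L, floor(cy - reach)); i1 <- min(npx, ceiling(cy + reach))
  if (j0 > j1 || i0 > i1) return(img)
  jj <- j0:j1; ii <- i0:i1
  px <- (matrix(jj - 0.5, length(ii), length(jj), byrow = TRUE) - cx) / scale
  py <- (matrix(ii - 0.5, length(ii), length(jj)) - cy) / scale
  u <- px * cos(psi) + py * sin(psi)
  v <- -px * sin(psi) + py * cos(psi)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  if (!is.null(wings)) {
    hx <- -WING_HINGE_FRAC * a       # hinge in body coordinates
    wlen <- WING_LEN_FRAC * a
    for (s in c(1, -1)) {            # +1 left, -1 right
      wang <- if (s > 0) wings[1] else wings[2]
      # wing direction: tail direction rotated by the wing angle, left
      # wings toward +v, right wings toward -v in body coordinates
      dirU <- -cos(wang); dirV <- s * sin(wang)
      du <- u - hx; dv <- v
      t <- pmin(pmax(du * dirU + dv * dirV, 0), wlen)
      dist2 <- (du - t * dirU)^2 + (dv - t * dirV)^2
      mask <- mask | (dist2 <= WING_HALFWIDTH_MM^2 & t > 0)
    }
  }
  sub <- img[ii, jj, drop = FALSE]
  sub[mask] <- flyLevel
  img[ii, jj] <- sub
  img
}

#' Write / read a rendered frame stack as PNG files
#'
#' Frames are written as \code{frame_000000.png} (0-based frame numbers)
#' in \code{dir}, 8-bit grayscale; the ground-truth table, when given, as
#' \code{truth.csv}.
#'
#' @param rendered output of \code{\link{renderTrial}}.
#' @param dir output directory (created if needed).
#' @param frameNumbers 0-based frame numbers (default from the truth).
#' @return \code{writeFrames}: invisibly, the file paths.
#'   \code{readFrames}: list(frames, truth) as in
#'   \code{\link{renderTrial}} (truth NULL when absent).
#' @export
writeFrames <- function(rendered, dir, frameNumbers = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- rendered$frames
  if (is.null(frameNumbers)) frameNumbers <- rendered$truth$frame
  n <- dim(st)[3]
  paths <- character(n)
  for (k in seq_len(n)) {
    paths[k] <- file.path(dir, sprintf("frame_%06d.png", frameNumbers[k]))
    png::writePNG(st[, , k] / 255, paths[k])
  }
  if (!is.null(rendered$truth))
    utils::write.csv(rendered$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(paths)
}

#' @rdname writeFrames
#' @export
readFrames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame PNGs found in ", dir)
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 3) first <- first[, , 1]
  st <- array(0, dim = c(nrow(first), ncol(first), length(files)))
  st[, , 1] <- first * 255
  for (k in seq_along(files)[-1]) {
    im <- png::readPNG(files[k])
    if (length(dim(im)) == 3) im <- im[, , 1]
    st[, , k] <- im * 255
  }
  tr <- file.path(dir, "truth.csv")
  truth <- if (file.exists(tr)) utils::read.csv(tr) else NULL
  frameNumbers <- as.integer(sub("^frame_(\\d+)\\.png$", "\\1",
                                 basename(files)))
  list(frames = st, truth = truth, frameNumbers = frameNumbers)
}
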