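FEATURE_COLS <- c("dist_mm", "ddist_mm_s", "speed_mm_s", "sideways_mm_s",
                  "angspeed_rad_s", "heading_err_rad", "theta_rad",
                  "cos_theta", "wing_l_rad", "wing_r_rad", "wing_max_rad",
                  "win_dist_mm", "win_speed_mm_s", "win_sideways_mm_s",
                  "win_angspeed_rad_s", "win_heading_err_rad",
                  "win_wing_max_rad")

# rolling mean over +-halfWin frames, partial windows at the edges,
# NA-aware (gap frames contribute nothing)
rollMean <- function(x, halfWin = 5) {
  n <- length(x)
  miss <- is.na(x)
  xs <- x; xs[miss] <- 0
  cs <- c(0, cumsum(xs)); cn <- c(0, cumsum(!miss))
  lo <- pmax(seq_len(n) - halfWin, 1)
  hi <- pmin(seq_len(n) + halfWin, n)
  num <- cs[hi + 1] - cs[lo]
  den <- cn[hi + 1] - cn[lo]
  ifelse(den > 0, num / den, NA_real_)
}

#' Per-frame classifier features from a tracked trial
#'
#' Computes the package's normative feature set from tracking data, one
#' row per non-gap frame: male-female centroid distance and its rate of
#' change, translational / sideways / angular speed, heading error (angle
#' between the male heading and the male-to-female direction), the male's
#' angular position theta around the female (plus its cosine, an
#' anterior-posterior score), wing angles and their maximum, and
#' short-window (+-5 frame) means of the kinematic features. Windowed
#' features use only the frames available near the trial edges and skip
#' gap frames.
#'
#' @param trial a \linkS4class{TrackedTrial}.
#' @param halfWin window half-width in frames (default 5).
#' @return data.frame with columns frame plus the features; zero rows if
#'   every frame is a gap.
#' @export
computeFeatures <- function(trial, halfWin = 5) {
  p <- trial@poses
  n <- nrow(p)
  if (n < 2 * halfWin + 1)
    stop("computeFeatures needs at least ", 2 * halfWin + 1, " frames")
  fps <- trial@frameRate
  x <- p$male_x_mm; y <- p$male_y_mm
  x[p$gap] <- NA; y[p$gap] <- NA
  dxf <- p$female_x_mm - x; dyf <- p$female_y_mm - y
  dist <- sqrt(dxf^2 + dyf^2)
  vx <- centralDiff(x) * fps; vy <- centralDiff(y) * fps
  speed <- sqrt(vx^2 + vy^2)
  # sideways: velocity component perpendicular to the male->female vector
  ux <- dxf / dist; uy <- dyf / dist
  sideways <- abs(vx * uy - vy * ux)
  orient <- p$male_orientation_rad; orient[p$gap] <- NA
  angspeed <- abs(centralDiffAngle(orient)) * fps
  headingErr <- abs(wrapAngle(orient - atan2(dyf, dxf)))
  theta <- wrapAngle(atan2(-dyf, -dxf) - trial@anteriorDirection)
  wl <- p$male_wing_l_rad; wr <- p$male_wing_r_rad
  wl[p$gap] <- NA; wr[p$gap] <- NA
  wmax <- pmax(wl, wr)
  ddist <- centralDiff(dist) * fps
  feat <- data.frame(
    frame = p$frame,
    dist_mm = dist, ddist_mm_s = ddist, speed_mm_s = speed,
    sideways_mm_s = sideways, angspeed_rad_s = angspeed,
    heading_err_rad = headingErr, theta_rad = theta, cos_theta = cos(theta),
    wing_l_rad = wl, wing_r_rad = wr, wing_max_rad = wmax,
    win_dist_mm = rollMean(dist, halfWin),
    win_speed_mm_s = rollMean(speed, halfWin),
    win_sideways_mm_s = rollMean(sideways, halfWin),
    win_angspeed_rad_s = rollMean(angspeed, halfWin),
    win_heading_err_rad = rollMean(headingErr, halfWin),
    win_wing_max_rad = rollMean(wmax, halfWin))
  feat[!p$gap & stats::complete.cases(feat), , drop = FALSE]
}

## ---- discrete AdaBoost over depth-1 rpart stumps -------------------------

# extract the stump decision from a depth-1 rpart fit; NULL if no split
stumpRule <- function(fit) {
  s <- fit$splits
  if (is.null(s) || nrow(s) == 0) return(NULL)
  fr <- fit$frame
  leftClass <- fr$yval[rownames(fr) == "2"]
  rightClass <- fr$yval[rownames(fr) == "3"]
  list(var = rownames(s)[1], thr = s[1, "index"], ncat = s[1, "ncat"],
       left = leftClass, right = rightClass)
}

applyStump <- function(rule, X, lv) {
  x <- X[[rule$var]]
  goLeft <- if (rule$ncat < 0) x < rule$thr else x >= rule$thr
  cls <- ifelse(goLeft, rule$left, rule$right)
  ifelse(cls == match("pos", lv), 1, -1)
}

# y in {-1, +1}; returns list of (rule, alpha)
adaboostFit <- function(X, y, nTrees = 100) {
  n <- length(y)
  w <- rep(1 / n, n)
  yf <- factor(ifelse(y > 0, "pos", "neg"), levels = c("neg", "pos"))
  lv <- levels(yf)
  dat <- cbind(X, .y = yf)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  ensemble <- list()
  for (m in seq_len(nTrees)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctrl)
    rule <- stumpRule(fit)
    if (is.null(rule)) break                     # no usable split left
    pred <- applyStump(rule, X, lv)
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    if (err < 1e-10) {
      ensemble[[length(ensemble) + 1L]] <- list(rule = rule, alpha = 15)
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    ensemble[[length(ensemble) + 1L]] <- list(rule = rule, alpha = alpha)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
  }
  ensemble
}

adaboostScore <- function(ensemble, X) {
  if (!length(ensemble)) return(rep(0, nrow(X)))
  lv <- c("neg", "pos")
  F <- rep(0, nrow(X)); A <- 0
  for (st in ensemble) {
    F <- F + st$alpha * applyStump(st$rule, X, lv)
    A <- A + st$alpha
  }
  F / A                                          # normalized margin in [-1, 1]
}

#' Train per-behavior boosted-stump classifiers with grouped CV
#'
#' One binary discrete-AdaBoost ensemble of depth-1 decision stumps per
#' courtship element (tapping, scissoring, orienting), evaluated by
#' trial-grouped k-fold cross-validation: all frames of a trial stay in
#' the same fold, so no video leaks across folds. The returned model set
#' is refit on all data.
#'
#' @param features feature data.frame (columns as
#'   \code{\link{computeFeatures}}; extra columns are ignored).
#' @param labels factor of per-frame labels (levels including the three
#'   elements; anything else counts as negative).
#' @param groups trial identifiers, one per frame (grouping unit for CV).
#' @param nFolds folds (default 4).
#' @param nTrees stumps per ensemble (default 100).
#' @param seed RNG seed for fold assignment.
#' @return object of class \code{courtshipClassifier}: list(models,
#'   cv = data.frame(behavior, accuracy), featureNames, nTrees).
#' @export
trainClassifier <- function(features, labels, groups, nFolds = 4,
                            nTrees = 100, seed = 1) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("labels contain a single class; nothing to train")
  for (b in COURTSHIP_ELEMENTS)
    if (!any(labels == b))
      stop("no training examples for behavior: ", b)
  X <- features[, intersect(FEATURE_COLS, names(features)), drop = FALSE]
  stopifnot(nrow(X) == length(labels), length(groups) == length(labels))
  set.seed(seed)
  ug <- unique(groups)
  if (length(ug) < nFolds)
    stop("need at least ", nFolds, " trials for ", nFolds, "-fold grouped CV")
  foldOf <- stats::setNames(sample(rep_len(seq_len(nFolds), length(ug))), ug)
  fold <- foldOf[as.character(groups)]

  cv <- data.frame(behavior = COURTSHIP_ELEMENTS,
                   accuracy = NA_real_)
  models <- list()
  for (b in COURTSHIP_ELEMENTS) {
    y <- ifelse(labels == b, 1, -1)
    correct <- 0; total <- 0
    for (f in seq_len(nFolds)) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[tr])) < 2)
        stop("behavior ", b, " missing from a training fold")
      ens <- adaboostFit(X[tr, , drop = FALSE], y[tr], nTrees)
      pred <- ifelse(adaboostScore(ens, X[te, , drop = FALSE]) > 0, 1, -1)
      correct <- correct + sum(pred == y[te]); total <- total + sum(te)
    }
    cv$accuracy[cv$behavior == b] <- correct / total
    models[[b]] <- adaboostFit(X, y, nTrees)
  }
  structure(list(models = models, cv = cv, featureNames = names(X),
                 nTrees = nTrees),
            class = "courtshipClassifier")
}

#' @export
print.courtshipClassifier <- function(x, ...) {
  cat("courtshipClassifier:", x$nTrees, "boosted stumps per behavior\n")
  for (i in seq_len(nrow(x$cv)))
    cat(sprintf("  %-11s CV accuracy %.3f\n", x$cv$behavior[i],
                x$cv$accuracy[i]))
  invisible(x)
}

#' Per-behavior raw scores for a feature table
#'
#' @param classifier a \code{courtshipClassifier}.
#' @param features feature data.frame.
#' @return numeric matrix (nrow x 3) of normalized margins, columns
#'   tapping, scissoring, orienting; positive = behavior present.
#' @export
predictScores <- function(classifier, features) {
  X <- features[, classifier$featureNames, drop = FALSE]
  out <- vapply(COURTSHIP_ELEMENTS, function(b)
    adaboostScore(classifier$models[[b]], X), numeric(nrow(X)))
  matrix(out, nrow = nrow(X), dimnames = list(NULL, COURTSHIP_ELEMENTS))
}

#' Apply the behavior precedence hierarchy
#'
#' Classifications are made mutually exclusive per frame by precedence:
#' active tapping first, then stationary scissoring, then stationary
#' orienting; a frame with no positive score is "none". Applying the
#' hierarchy to an already-collapsed label factor returns it unchanged
#' (idempotence at the label level).
#'
#' @param scores numeric matrix with columns tapping/scissoring/orienting
#'   (positive score = behavior detected), or a label factor.
#' @return factor of per-frame labels.
#' @export
applyHierarchy <- function(scores) {
  if (is.factor(scores))
    return(factor(as.character(scores), levels = BEHAVIOR_LEVELS))
  stopifnot(all(COURTSHIP_ELEMENTS %in% colnames(scores)))
  lab <- rep("none", nrow(scores))
  for (b in rev(COURTSHIP_ELEMENTS))   # lowest precedence first
    lab[scores[, b] > 0] <- b
  factor(lab, levels = BEHAVIOR_LEVELS)
}

#' Mask labels by annotated courtship bouts
#'
#' Positive classifications outside the hand-annotated courtship bouts
#' are discarded (set to "none"), and the bout-membership flag is set.
#'
#' @param labels factor of per-frame labels (or a
#'   \linkS4class{BehaviorLabels}, whose labels are reused).
#' @param bouts data.frame(start_frame, end_frame), half-open 0-based
#'   intervals, sorted and non-overlapping.
#' @param nFrames trial length in frames (default: length of labels).
#' @param scores optional raw score matrix to carry along.
#' @return a \linkS4class{BehaviorLabels}.
#' @export
maskByBouts <- function(labels, bouts, nFrames = NULL, scores = NULL) {
  if (is(labels, "BehaviorLabels")) labels <- labels@label
  labels <- factor(as.character(labels), levels = BEHAVIOR_LEVELS)
  n <- if (is.null(nFrames)) length(labels) else nFrames
  if (length(labels) != n) stop("labels length does not match nFrames")
  if (nrow(bouts)) {
    if (any(bouts$start_frame < 0) || any(bouts$end_frame > n))
      stop("bout indices beyond trial length")
    if (any(bouts$end_frame <= bouts$start_frame))
      stop("bouts must be non-empty half-open intervals")
  }
  inBout <- logical(n)
  for (i in seq_len(nrow(bouts)))
    inBout[(bouts$start_frame[i] + 1):bouts$end_frame[i]] <- TRUE
  labels[!inBout] <- "none"
  if (is.null(scores)) scores <- matrix(numeric(0), 0, 3)
  new("BehaviorLabels", label = labels, scores = scores, inBout = inBout,
      bouts = bouts[order(bouts$start_frame), , drop = FALSE])
}

#' Classify a tracked trial
#'
#' Runs feature computation, per-behavior scoring, the precedence
#' hierarchy, and bout masking. Gap frames get label "none".
#'
#' @param classifier a \code{courtshipClassifier}.
#' @param trial a \linkS4class{TrackedTrial}.
#' @param bouts courtship-bout annotation data.frame.
#' @return a \linkS4class{BehaviorLabels}.
#' @export
classifyTrial <- function(classifier, trial, bouts) {
  feat <- computeFeatures(trial)
  n <- nrow(trial@poses)
  scores <- matrix(-1, n, 3, dimnames = list(NULL, COURTSHIP_ELEMENTS))
  if (nrow(feat)) {
    idx <- match(feat$frame, trial@poses$frame)
    scores[idx, ] <- predictScores(classifier, feat)
  }
  maskByBouts(applyHierarchy(scores), bouts, n, scores = scores)
}
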