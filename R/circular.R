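#' Circular helpers and the (bimodal) Rayleigh test
#'
#' Angles are radians throughout the package, measured in the female-centered
#' frame with the female's anterior at 0, wrapped to (-pi, pi],
#' counterclockwise positive in image coordinates.
#'
#' @name circular
NULL

#' Wrap angles to (-pi, pi]
#' @param x angles (rad).
#' @return wrapped angles in (-pi, pi].
#' @export
wrapAngle <- function(x) pi - ((pi - x) %% (2 * pi))

#' Circular mean and resultant length
#'
#' @param x angles (rad); NA values are dropped.
#' @return \code{circMean}: mean direction in (-pi, pi].
#'   \code{circR}: mean resultant length in [0, 1].
#' @export
circMean <- function(x) {
  x <- x[!is.na(x)]
  atan2(mean(sin(x)), mean(cos(x)))
}

#' @rdname circMean
#' @export
circR <- function(x) {
  x <- x[!is.na(x)]
  min(1, sqrt(mean(cos(x))^2 + mean(sin(x))^2))
}

# Fisher's approximation to the inverse of A(kappa) = I1/I0.
kappaFromR <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Standard error of a circular mean
#'
#' Large-sample circular standard error 1/sqrt(n R kappa_hat), with kappa
#' estimated by Fisher's approximation. Used for "within 3 circular-SEM"
#' recovery checks.
#' @param x angles (rad).
#' @return standard error (rad).
#' @export
circSEM <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x); r <- circR(x)
  if (n < 2 || r <= 0) return(NA_real_)
  1 / sqrt(n * r * kappaFromR(r))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. \code{kappa = 0} gives the circular
#' uniform; \code{kappa = Inf} degenerates to \code{mu} exactly.
#'
#' @param n sample size.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0, may be Inf).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  stopifnot(kappa >= 0)
  if (kappa == 0) return(wrapAngle(stats::runif(n, -pi, pi)))
  if (!is.finite(kappa))
    return(rep(if (mu > pi || mu <= -pi) wrapAngle(mu) else mu, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k) {
      out[(got + 1):(got + k)] <- sign(u3[ok] - 0.5) * acos(f[ok]) + mu
      got <- got + k
    }
  }
  wrapAngle(out)
}

# Sample from a scenario angular law: plain von Mises or an equal-weight
# axial mixture at mu and mu + pi (balanced split, alternating assignment).
sampleAngularLaw <- function(n, law) {
  if (n == 0) return(numeric(0))
  type <- if (is.null(law$type)) "vonmises" else law$type
  if (type == "vonmises") return(rvonmises(n, law$mu, law$kappa))
  # axial: equal mixture of von Mises at mu and mu + pi
  comp <- rep(c(0, pi), length.out = n)[sample.int(n)]
  wrapAngle(rvonmises(n, law$mu, law$kappa) + comp)
}

#' Rayleigh test of circular uniformity
#'
#' Resultant length R = |sum exp(i theta)| / n, with the standard
#' large-sample approximation for the p-value,
#' p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n)).
#'
#' @param angles angles (rad), n >= 3.
#' @return a \linkS4class{CircularSummary} with \code{verdict = ""} (a plain
#'   test; use \code{\link{bimodalRayleighTest}} for the gated procedure).
#' @examples
#' rayleighTest(rvonmises(50, 0, 2))
#' @export
rayleighTest <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 3) stop("rayleighTest needs at least 3 angles")
  R <- circR(angles)
  Rn <- n * R
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  new("CircularSummary", meanAngle = circMean(angles), R = R,
      RAxial = NA_real_, n = n, pUnimodal = min(1, p), pAxial = NA_real_,
      verdict = "", alpha = NA_real_)
}

#' Gated bimodal (axial) Rayleigh test
#'
#' The raw angles are first tested for uniformity with the Rayleigh test.
#' If that is significant at \code{alpha} the distribution is called
#' unimodal and the axial stage is not run. Otherwise each angle t is
#' transformed by doubling, theta = 2t mod 2pi, and the Rayleigh test is
#' rerun on the transformed angles; a significant result is called
#' axial-bimodal (two modes separated by pi) with axis = (mean of the
#' doubled angles)/2, and a non-significant one uniform.
#'
#' @param angles angles (rad), n >= 3.
#' @param alpha significance level of the gate (default 0.05).
#' @return a \linkS4class{CircularSummary}; \code{pAxial} is NA whenever
#'   the axial stage did not run.
#' @examples
#' bimodalRayleighTest(c(rvonmises(30, pi/2, 4), rvonmises(30, -pi/2, 4)))
#' @export
bimodalRayleighTest <- function(angles, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  uni <- rayleighTest(angles)
  if (uni@pUnimodal < alpha) {
    return(new("CircularSummary", meanAngle = uni@meanAngle, R = uni@R,
               RAxial = NA_real_, n = uni@n, pUnimodal = uni@pUnimodal,
               pAxial = NA_real_, verdict = "unimodal", alpha = alpha))
  }
  doubled <- (2 * angles[!is.na(angles)]) %% (2 * pi)
  ax <- rayleighTest(doubled)
  if (ax@pUnimodal < alpha) {
    axis <- wrapAngle(ax@meanAngle) / 2   # axis in (-pi/2, pi/2]
    new("CircularSummary", meanAngle = axis, R = uni@R, RAxial = ax@R,
        n = uni@n, pUnimodal = uni@pUnimodal, pAxial = ax@pUnimodal,
        verdict = "axial-bimodal", alpha = alpha)
  } else {
    new("CircularSummary", meanAngle = uni@meanAngle, R = uni@R,
        RAxial = ax@R, n = uni@n, pUnimodal = uni@pUnimodal,
        pAxial = ax@pUnimodal, verdict = "uniform", alpha = alpha)
  }
}
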