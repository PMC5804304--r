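## Arcuate trajectory model
##
## A nerve fiber track boundary (or centerline) is constrained to
##   phi(r) = a + b * (r - r0)^c ,   r >= r0
## with phi the angular position in degrees, a the angle at the reference
## radius r0 (0.85 mm, the disc-rim anchor circle), b real, and c in (0.05, 5]
## controlling how quickly the arc bends with radius.

#' Construct an arcuate trajectory model
#'
#' @param a angular position (degrees) at the reference radius `r0`
#' @param b arc coefficient (degrees / mm^c)
#' @param c positive exponent, constrained to (0.05, 5]
#' @param r0 reference radius in mm (default 0.85, the 1.7-mm anchor circle)
#' @param zero_b logical flag: TRUE when the track is radial and the exponent
#'   is unidentifiable (reported as c = 1)
#' @return object of class `arcuate_model`
#' @export
arcuate_model <- function(a, b, c, r0 = 0.85, zero_b = FALSE) {
  if (!is.finite(c) || c <= 0) stop("exponent c must be positive")
  structure(list(a = a, b = b, c = c, r0 = r0, zero_b = isTRUE(zero_b)),
            class = "arcuate_model")
}

#' Evaluate an arcuate model
#'
#' @param model an `arcuate_model`
#' @param r radii in mm, all >= `model$r0`
#' @return angular positions in degrees
#' @export
eval_arcuate <- function(model, r) {
  if (any(r < model$r0 - 1e-12)) {
    stop("arcuate model is defined only for r >= r0 = ", model$r0)
  }
  model$a + model$b * pmax(r - model$r0, 0)^model$c
}

#' Extrapolate an arcuate model beyond the fitted annulus
#'
#' Evaluates the fitted model outside the 1.5-3.5 mm measurement annulus,
#' down to the anchor circle at r0 and outward up to a configurable cap
#' (default 3.5 mm + 0.5 mm margin). Extrapolation far beyond the measured
#' area amplifies any trajectory error and is refused.
#'
#' @inheritParams eval_arcuate
#' @param r_target radii in mm
#' @param r_cap outward extrapolation limit in mm
#' @return angular positions in degrees
#' @export
extrapolate_model <- function(model, r_target, r_cap = 4.0) {
  if (any(r_target < model$r0 - 1e-12)) {
    stop("cannot extrapolate inward of the anchor radius r0 = ", model$r0)
  }
  if (any(r_target > r_cap + 1e-12)) {
    stop("extrapolation limit exceeded: r = ", max(r_target),
         " mm is beyond the cap of ", r_cap, " mm")
  }
  eval_arcuate(model, r_target)
}

#' Skew angle of a track at radius r
#'
#' The angle beta between the fiber course and the radial direction follows
#' analytically from the arcuate model: tan(beta) = r * dphi/dr with phi in
#' radians, dphi/dr = b * c * (r - r0)^(c - 1).
#'
#' @inheritParams eval_arcuate
#' @return beta in degrees, |beta| < 90
#' @export
beta_from_model <- function(model, r) {
  if (any(r < model$r0 - 1e-12)) {
    stop("beta is defined only for r >= r0 = ", model$r0)
  }
  if (model$b == 0) return(rep(0, length(r)))
  dr <- r - model$r0
  # dphi/dr in degrees/mm; at r = r0 the derivative is 0 (c > 1), finite
  # (c = 1) or diverges (c < 1), where beta tends to +/-90
  dphi <- model$b * model$c * dr^(model$c - 1)
  dphi[dr == 0 & model$c > 1] <- 0
  rad2deg(atan(r * deg2rad(dphi)))
}

## residual sum of squares of the linear (a, b) subproblem at fixed c
.arcuate_profile_rss <- function(cc, r, phi, r0) {
  x <- (r - r0)^cc
  xm <- mean(x); pm <- mean(phi)
  sxx <- sum((x - xm)^2)
  if (sxx < 1e-300) return(sum((phi - pm)^2))
  b <- sum((x - xm) * (phi - pm)) / sxx
  a <- pm - b * xm
  sum((phi - a - b * x)^2)
}

#' Fit the arcuate model to sampled boundary angles
#'
#' Least-squares fit of phi(r) = a + b (r - r0)^c by profiling: for fixed c
#' the problem is linear in (a, b), so c is found by bounded one-dimensional
#' minimization with multiple starting brackets (exponent fits are
#' ill-conditioned for near-radial tracks), then (a, b) by closed form.
#'
#' @param r radii in mm (at least 5 finite samples)
#' @param phi angular positions in degrees
#' @param r0 reference radius in mm
#' @param c_bounds allowed exponent range (default (0.05, 5])
#' @return an `arcuate_model` with attributes `rms` (residual RMS, degrees)
#'   and `converged`
#' @export
fit_arcuate_model <- function(r, phi, r0 = 0.85, c_bounds = c(0.05, 5)) {
  ok <- is.finite(r) & is.finite(phi)
  r <- r[ok]; phi <- phi[ok]
  if (length(r) < 5) stop("need at least 5 finite samples to fit")
  if (any(r < r0)) stop("all radii must be >= r0")

  # radial track: constant angle, exponent unidentifiable
  if (max(phi) - min(phi) < 1e-10) {
    m <- arcuate_model(mean(phi), 0, 1, r0, zero_b = TRUE)
    attr(m, "rms") <- sqrt(mean((phi - mean(phi))^2))
    attr(m, "converged") <- TRUE
    return(m)
  }

  lo <- c_bounds[1]; hi <- c_bounds[2]
  # multi-start brackets around c = 0.5, 1, 2
  brackets <- list(c(lo, 1.1), c(0.4, 2.3), c(1.6, hi))
  best <- NULL
  for (br in brackets) {
    o <- stats::optimize(.arcuate_profile_rss, interval = br,
                         r = r, phi = phi, r0 = r0, tol = 1e-9)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  # polish in a narrow bracket around the best exponent
  w <- 0.05 * (hi - lo)
  o <- stats::optimize(.arcuate_profile_rss,
                       interval = c(max(lo, best$minimum - w),
                                    min(hi, best$minimum + w)),
                       r = r, phi = phi, r0 = r0, tol = 1e-12)
  if (o$objective < best$objective) best <- o

  cc <- best$minimum
  x <- (r - r0)^cc
  xm <- mean(x); pm <- mean(phi)
  b <- sum((x - xm) * (phi - pm)) / sum((x - xm)^2)
  a <- pm - b * xm
  converged <- TRUE
  if (!is.finite(a) || !is.finite(b)) {
    # fall back to the linear model c = 1
    cc <- 1
    x <- r - r0
    b <- stats::cov(x, phi) / stats::var(x)
    a <- mean(phi) - b * mean(x)
    converged <- FALSE
  }
  m <- arcuate_model(a, b, cc, r0, zero_b = abs(b) < 1e-8)
  attr(m, "rms") <- sqrt(best$objective / length(r))
  attr(m, "converged") <- converged
  m
}

#' @export
print.arcuate_model <- function(x, ...) {
  cat(sprintf("arcuate_model: phi(r) = %.4f + %.4f (r - %.2f)^%.4f deg%s\n",
              x$a, x$b, x$r0, x$c, if (x$zero_b) " [radial]" else ""))
  invisible(x)
}
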