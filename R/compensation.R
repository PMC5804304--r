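## Macular ganglion-cell flux compensation
##
## Nerve fiber flux is conserved along a track only where no fibers
## originate on retinal ganglion cells (RGC). On the temporal side the
## tracks run into the macula, where the RGC density is high: as fibers
## terminate on their somas, flux is lost with increasing radius. Assuming
## the flux reduction is proportional to the RGC count integrated over the
## track footprint, the compensation coefficient
##   gamma_n(r) = 1 / (1 - L_n(r) / N_n)
## exactly restores a conserved quantity, where L_n(r) is the RGC count
## between the innermost analysis ring and r, and N_n the count out to the
## track's outer extent (map plus a beyond-map allowance). Outside the
## 110-270 degree temporal zone the RGC density is negligible and gamma is
## fixed at 1.

#' Parametric retinal ganglion cell density model
#'
#' Radially symmetric, foveally peaked profile: zero inside the foveal pit,
#' quadratic rise to a peak ring, exponential decay outside. A parametric
#' stand-in for histology-derived density maps, adequate for flux
#' compensation which only depends on relative density along tracks.
#'
#' @param peak_density peak density in cells/mm^2
#' @param pit_radius RGC-free foveal pit radius in mm
#' @param peak_radius eccentricity of the density peak in mm
#' @param decay_scale exponential decay scale beyond the peak in mm
#' @param fovea_center (x, y) position of the fovea in mm
#' @return object of class `rgc_density_model`
#' @export
rgc_density_model <- function(peak_density = 35000, pit_radius = 0.2,
                              peak_radius = 1.7, decay_scale = 1.5,
                              fovea_center = c(-4, 0)) {
  stopifnot(peak_density >= 0, pit_radius >= 0,
            peak_radius > pit_radius, decay_scale > 0)
  structure(list(peak_density = peak_density, pit_radius = pit_radius,
                 peak_radius = peak_radius, decay_scale = decay_scale,
                 fovea_center = as.numeric(fovea_center)),
            class = "rgc_density_model")
}

## density as a function of eccentricity (mm)
rgc_density_ecc <- function(e, model) {
  d <- numeric(length(e))
  ramp <- e > model$pit_radius & e <= model$peak_radius
  d[ramp] <- model$peak_density *
    ((e[ramp] - model$pit_radius) / (model$peak_radius - model$pit_radius))^2
  tail <- e > model$peak_radius
  d[tail] <- model$peak_density *
    exp(-(e[tail] - model$peak_radius) / model$decay_scale)
  d
}

#' RGC density at a fundus point
#'
#' @param point (x, y) in mm fundus coordinates, or a 2-column matrix
#' @param model an `rgc_density_model`
#' @return density in cells/mm^2
#' @export
rgc_density <- function(point, model) {
  p <- matrix(as.numeric(point), ncol = 2)
  e <- sqrt((p[, 1] - model$fovea_center[1])^2 +
            (p[, 2] - model$fovea_center[2])^2)
  rgc_density_ecc(e, model)
}

#' Total RGC count implied by the density model
#'
#' Closed-form integral of the radial profile over the plane; used to check
#' that the parametric profile carries a plausible total cell count.
#'
#' @param model an `rgc_density_model`
#' @return total cell count
#' @export
rgc_total_count <- function(model) {
  p <- model$pit_radius; k <- model$peak_radius; s <- model$decay_scale
  w <- k - p
  # ramp: 2*pi*peak * int_p^k e ((e-p)/w)^2 de, substituting u = e - p
  ramp <- 2 * pi * model$peak_density * (w^2 / 4 + p * w / 3)
  # tail: 2*pi*peak * int_k^inf e exp(-(e-k)/s) de = 2*pi*peak*s*(k+s)
  tail <- 2 * pi * model$peak_density * s * (k + s)
  ramp + tail
}

#' Per-track RGC termination fraction
#'
#' For each of the 64 tracks of a trajectory map, integrates the RGC density
#' over the track footprint (width x arc at the track centerline) along a
#' fine radial grid, giving the fraction L_n(r)/N_n of the track's fibers
#' that have terminated between the innermost ring and radius r. The outer
#' extent `r_beyond` adds the beyond-map allowance.
#'
#' @param traj reference `trajectory_map`
#' @param rgc an `rgc_density_model` (its `fovea_center` is interpreted in
#'   the canonical registered frame, i.e. the fovea lies at
#'   (-fovea_distance, 0))
#' @param r radii (mm) at which the fraction is wanted
#' @param r_in innermost ring radius (integration start)
#' @param r_beyond outer integration extent in mm
#' @param dr integration step in mm
#' @return matrix [64 x length(r)] of termination fractions in [0, 1)
#' @export
track_termination_fraction <- function(traj, rgc, r = default_radii(),
                                       r_in = min(default_radii()),
                                       r_beyond = 6.0, dr = 0.02) {
  rf <- seq(r_in, r_beyond, by = dr)
  cl <- centerline_angles(traj, rf)              # [64 x nf] degrees
  bb <- boundary_angles(traj, rf)
  nxt <- c(2:64, 1)
  up <- bb[nxt, , drop = FALSE]
  up[64, ] <- up[64, ] + 360
  # track widths, radians; clamped at zero where the extrapolated borders
  # pinch beyond the measured annulus (the arcuate model is only trusted
  # where tracks stay disjoint, and the pinching tracks are far from the
  # macula where the RGC density is negligible)
  w <- pmax(deg2rad(up - bb), 0)
  # centerline positions in the canonical frame (fovea at rgc$fovea_center)
  px <- sweep(cos(deg2rad(cl)), 2, rf, `*`)
  py <- sweep(sin(deg2rad(cl)), 2, rf, `*`)
  e <- sqrt((px - rgc$fovea_center[1])^2 + (py - rgc$fovea_center[2])^2)
  dens <- matrix(rgc_density_ecc(e, rgc), nrow = 64)
  lam <- dens * w * sweep(matrix(1, 64, length(rf)), 2, rf, `*`)
  # cumulative trapezoid along the radius
  mid <- (lam[, -1, drop = FALSE] + lam[, -ncol(lam), drop = FALSE]) / 2 * dr
  L <- cbind(0, t(apply(mid, 1, cumsum)))
  N <- L[, ncol(L)]
  frac <- matrix(0, 64, length(r))
  for (n in 1:64) {
    if (N[n] > 0) {
      frac[n, ] <- stats::approx(rf, L[n, ] / N[n], xout = r, rule = 2)$y
    }
  }
  frac
}

#' Macular compensation coefficient map
#'
#' Builds the gamma(r, theta) map from a reference (healthy) trajectory and
#' an RGC density model: per track, gamma_n(r) = 1/(1 - L_n(r)/N_n);
#' interpolated in angle between track centerlines (periodic), then clamped
#' to exactly 1 outside the temporal zone (default 110-270 degrees) where
#' RGC density is assumed negligible.
#'
#' @inheritParams track_termination_fraction
#' @param radii ring radii of the output map
#' @param n_theta angular samples
#' @param zone_deg angular span (degrees) inside which compensation applies
#' @return `polar_annulus_map` of quantity "gamma"
#' @export
compensation_map <- function(traj, rgc, radii = default_radii(),
                             n_theta = 1024L, zone_deg = c(110, 270),
                             r_beyond = 6.0, dr = 0.02) {
  frac <- track_termination_fraction(traj, rgc, r = radii,
                                     r_in = min(radii),
                                     r_beyond = r_beyond, dr = dr)
  if (any(frac >= 1)) {
    stop("RGC model inconsistent with flux: termination fraction reached 1")
  }
  gam_track <- 1 / (1 - frac)                    # [64 x n_rings]
  theta <- theta_grid(n_theta)
  cl <- centerline_angles(traj, radii)           # [64 x n_rings]
  out <- matrix(1, length(radii), n_theta)
  for (i in seq_along(radii)) {
    x <- cl[, i]; y <- gam_track[, i]
    o <- order(x)
    x <- x[o]; y <- y[o]
    # periodic closure across 0/360
    xx <- c(x[length(x)] - 360, x, x[1] + 360)
    yy <- c(y[length(y)], y, y[1])
    out[i, ] <- stats::approx(xx, yy, xout = theta, ties = mean)$y
  }
  out[, theta < zone_deg[1] | theta > zone_deg[2]] <- 1
  out[out < 1] <- 1
  polar_annulus_map(out, radii = radii, quantity = "gamma")
}
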