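## Flux tracing core: flux density, equal-flux division, trajectory map,
## skew (cos beta) map, and the iterative tracing loop.
##
## The guiding principle is a two-dimensional analogue of Gauss' flux
## theorem: the perpendicular cross-sectional area of nerve fibers (the
## nerve fiber flux, NFF) crossing a sampling circle,
##   dPhi(r, theta) = T(r, theta) * cos(beta(r, theta)) * r * dtheta ,
## is conserved along a fiber bundle wherever no fibers originate on retinal
## ganglion cells. Dividing each sampling circle into equal-flux tracks and
## re-estimating the skew angle beta from the resulting trajectories yields a
## fixed point that is the nerve fiber trajectory map.

#' Flux density map
#'
#' Converts an NFL thickness map (um) into flux per angular bin (mm^2):
#' dPhi = (T/1000) * gamma * cos(beta) * r * dtheta.
#'
#' @param thickness registered `polar_annulus_map` of thickness (um)
#' @param cos_beta optional `polar_annulus_map` (or matrix) of cos(beta);
#'   defaults to 1 (radial fibers)
#' @param gamma optional `polar_annulus_map` (or matrix) of the macular
#'   compensation coefficient; defaults to 1
#' @return `polar_annulus_map` of quantity "flux_density" (mm^2 per bin)
#' @export
flux_density <- function(thickness, cos_beta = NULL, gamma = NULL) {
  stopifnot(inherits(thickness, "polar_annulus_map"))
  if (any(thickness$values < 0)) stop("negative thickness values")
  v <- thickness$values / 1000          # um -> mm
  cb <- if (is.null(cos_beta)) 1 else map_values(cos_beta)
  gm <- if (is.null(gamma)) 1 else map_values(gamma)
  dtheta <- 2 * pi / ncol(thickness$values)
  v <- v * cb * gm * thickness$radii * dtheta
  polar_annulus_map(v, radii = thickness$radii, quantity = "flux_density",
                    registered = thickness$registered)
}

map_values <- function(x) if (inherits(x, "polar_annulus_map")) x$values else x

#' Ring flux
#'
#' Total flux (mm^2) of each sampling circle: the circle line integral of
#' the skew-corrected NFL cross-section.
#'
#' @param density `polar_annulus_map` of flux density
#' @return numeric vector, one total per ring
#' @export
ring_flux <- function(density) {
  stopifnot(inherits(density, "polar_annulus_map"))
  rowSums(density$values)
}

## invert a piecewise-linear cumulative flux C at knot positions `edges`;
## zero-density plateaus place the boundary at the plateau midpoint
invert_cumflux <- function(cum, edges, targets) {
  n <- length(cum)
  tol <- max(cum) * 1e-12
  out <- numeric(length(targets))
  for (j in seq_along(targets)) {
    t <- targets[j]
    i <- findInterval(t, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    if (t > cum[i] + tol) {
      # target strictly inside an increasing span: linear inversion
      out[j] <- edges[i] + (t - cum[i]) / (cum[i + 1] - cum[i]) *
        (edges[i + 1] - edges[i])
    } else {
      # target hits a knot value; if the cumulative is flat there (a
      # zero-density plateau), place the boundary at the plateau midpoint
      lo <- i
      while (lo > 1L && cum[lo - 1L] >= t - tol) lo <- lo - 1L
      out[j] <- (edges[lo] + edges[i]) / 2
    }
  }
  out
}

#' Divide one sampling circle into equal-flux tracks
#'
#' Splits each hemisphere of a ring's flux-density profile into `n_tracks`
#' contiguous angular spans of equal flux by inverting the piecewise-linear
#' cumulative flux. Hemisphere borders are fixed at exactly 0 and 180
#' degrees; tracks never cross the midline.
#'
#' @param bin_flux flux per angular bin (mm^2) over the full circle, sampled
#'   at [theta_grid()] bin centers
#' @param theta bin-center angles in degrees
#' @param n_tracks tracks per hemisphere (default 32)
#' @return list with components `superior` and `inferior`, each a vector of
#'   `n_tracks + 1` boundary angles (degrees) including the fixed hemisphere
#'   borders
#' @export
divide_equal_flux <- function(bin_flux, theta = theta_grid(length(bin_flux)),
                              n_tracks = 32L) {
  if (any(bin_flux < 0)) stop("flux density must be nonnegative")
  hems <- hemisphere_bins(theta)
  out <- list()
  for (h in names(hems)) {
    idx <- hems[[h]]
    f <- bin_flux[idx]
    total <- sum(f)
    if (total <= 0) stop("zero hemisphere flux (", h, "): degenerate eye")
    base <- if (h == "superior") 0 else 180
    step <- 360 / length(theta)
    edges <- base + (0:length(idx)) * step
    cum <- c(0, cumsum(f))
    targets <- seq(0, total, length.out = n_tracks + 1)
    b <- invert_cumflux(cum, edges, targets)
    b[1] <- base
    b[length(b)] <- base + 180
    out[[h]] <- b
  }
  out
}

#' Trajectory map of 64 equal-flux tracks
#'
#' Assembles fitted boundary models into the package's trajectory container:
#' 64 border lines (index 1 is the fixed nasal midline at 0 degrees, 2-32
#' the superior interior borders, 33 the fixed temporal MPA border at 180
#' degrees, 34-64 the inferior interior borders). Track n spans borders n
#' and n + 1 (periodic); its centerline is the midpoint of the two borders
#' at each radius.
#'
#' @param boundaries list of 64 `arcuate_model` objects in angular order
#' @param radii radii (mm) over which the boundaries were fitted
#' @return object of class `trajectory_map`
#' @export
trajectory_map <- function(boundaries, radii = default_radii()) {
  stopifnot(length(boundaries) == 64)
  n_h <- 32L
  structure(
    list(boundaries = boundaries,
         radii = radii,
         n_tracks = 64L,
         hemisphere = rep(c("superior", "inferior"), each = n_h)),
    class = "trajectory_map")
}

#' @export
print.trajectory_map <- function(x, ...) {
  cat(sprintf("trajectory_map: %d tracks (32 per hemisphere), fitted over %.2f-%.2f mm\n",
              x$n_tracks, min(x$radii), max(x$radii)))
  invisible(x)
}

#' Boundary angles of all 64 borders at given radii
#'
#' @param traj a `trajectory_map`
#' @param r radii in mm
#' @return matrix [64 x length(r)] of angles in degrees
#' @export
boundary_angles <- function(traj, r) {
  m <- vapply(traj$boundaries, eval_arcuate, numeric(length(r)), r = r)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  t(m)
}

## derivative dphi/dr (deg/mm) of each border at radii r: [64 x length(r)]
boundary_dphi <- function(traj, r) {
  m <- vapply(traj$boundaries, function(mod) {
    if (mod$b == 0) return(rep(0, length(r)))
    dr <- pmax(r - mod$r0, 0)
    d <- mod$b * mod$c * dr^(mod$c - 1)
    d[dr == 0 & mod$c > 1] <- 0
    d
  }, numeric(length(r)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  t(m)
}

#' Centerline angles of all 64 tracks at given radii
#'
#' The centerline of a track is the midpoint of its two borders at each
#' radius.
#'
#' @inheritParams boundary_angles
#' @return matrix [64 x length(r)] of angles in degrees
#' @export
centerline_angles <- function(traj, r) {
  bb <- boundary_angles(traj, r)
  nxt <- c(2:64, 1)
  up <- bb[nxt, , drop = FALSE]
  # track 64 wraps from the last inferior border to 360 (= border 1)
  up[64, ] <- up[64, ] + 360
  (bb + up) / 2
}

## centerline skew angle beta (degrees) at radii r: analytic from the mean
## derivative of the two border models
centerline_beta <- function(traj, r) {
  dd <- boundary_dphi(traj, r)
  nxt <- c(2:64, 1)
  dmid <- (dd + dd[nxt, , drop = FALSE]) / 2
  rad2deg(atan(sweep(deg2rad(dmid), 2, r, `*`)))
}

## beta field on the (radii x theta) grid: per ring and hemisphere, linear
## interpolation in angle between track centerlines, clamped at the
## hemisphere borders
skew_beta_matrix <- function(traj, radii, theta = theta_grid()) {
  cl <- centerline_angles(traj, radii)
  cb <- centerline_beta(traj, radii)
  hems <- hemisphere_bins(theta)
  hem_tracks <- list(superior = 1:32, inferior = 33:64)
  out <- matrix(0, length(radii), length(theta))
  for (i in seq_along(radii)) {
    for (h in names(hems)) {
      tr <- hem_tracks[[h]]
      x <- cl[tr, i]
      y <- cb[tr, i]
      o <- order(x)
      out[i, hems[[h]]] <- stats::approx(x[o], y[o], xout = theta[hems[[h]]],
                                         rule = 2, ties = mean)$y
    }
  }
  out
}

#' Build the cos(beta) skew map from a trajectory map
#'
#' At each grid point, beta is interpolated linearly in angle between the
#' two nearest track centerlines within the hemisphere (clamped beyond the
#' first/last centerline), and the cosine is applied last.
#'
#' @param traj a `trajectory_map`
#' @param radii ring radii in mm
#' @param n_theta angular samples
#' @return `polar_annulus_map` of quantity "cos_beta"
#' @export
build_skew_map <- function(traj, radii = default_radii(), n_theta = 1024L) {
  theta <- theta_grid(n_theta)
  b <- skew_beta_matrix(traj, radii, theta)
  polar_annulus_map(cos(deg2rad(b)), radii = radii, quantity = "cos_beta")
}

## fit the 31 interior borders of one hemisphere from per-ring division
## results; `bmat` is [n_rings x 33] including the fixed borders
fit_hemisphere_boundaries <- function(bmat, radii, r0, c_bounds) {
  lapply(2:(ncol(bmat) - 1), function(j) {
    fit_arcuate_model(radii, bmat[, j], r0 = r0, c_bounds = c_bounds)
  })
}

#' Iterative equal-flux trajectory tracing
#'
#' Recovers the nerve fiber trajectory map from a registered NFL thickness
#' map by alternating: equal-flux division of each ring (per hemisphere),
#' arcuate-model fitting of the resulting border lines, skew-map
#' construction from the fitted trajectories, and flux-density
#' recomputation. The iteration starts from beta = 0 (radial fibers) and
#' stops when the full-grid maximum |change in beta| between iterations
#' drops below `tol_deg` (0.01 degrees), or at `max_iter`.
#'
#' @param thickness registered `polar_annulus_map` of thickness (um)
#' @param gamma optional macular compensation `polar_annulus_map` (healthy
#'   eyes only; identity when NULL)
#' @param n_tracks tracks per hemisphere
#' @param r0 arcuate-model reference radius (mm)
#' @param tol_deg convergence tolerance on max |delta beta| (degrees)
#' @param max_iter iteration cap
#' @param c_bounds exponent bounds for the arcuate fits
#' @param init optional `trajectory_map` to start from (its skew map seeds
#'   the first flux division in place of beta = 0)
#' @return list with components `trajectory` (`trajectory_map`), `cos_beta`
#'   (`polar_annulus_map`), `beta` (matrix, degrees), `iterations`,
#'   `converged`, `delta_history` (max |delta beta| per checked iteration),
#'   and `flagged` (TRUE when stopped by the divergence guard or iteration
#'   cap, or when fitted borders cross)
#' @export
trace_iterate <- function(thickness, gamma = NULL, n_tracks = 32L,
                          r0 = 0.85, tol_deg = 0.01, max_iter = 50L,
                          c_bounds = c(0.05, 5), init = NULL) {
  stopifnot(inherits(thickness, "polar_annulus_map"))
  if (!isTRUE(thickness$registered)) {
    stop("thickness map must be registered before tracing")
  }
  radii <- thickness$radii
  theta <- theta_grid(ncol(thickness$values))
  beta_prev <- if (is.null(init)) matrix(0, length(radii), length(theta)) else
    skew_beta_matrix(init, radii, theta)
  cosb <- cos(deg2rad(beta_prev))
  delta_history <- numeric(0)
  relax <- 1
  last_damp <- 0L
  traj <- NULL
  converged <- FALSE
  flagged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    dens <- flux_density(thickness, cos_beta = cosb, gamma = gamma)
    bsup <- matrix(NA_real_, length(radii), n_tracks + 1)
    binf <- matrix(NA_real_, length(radii), n_tracks + 1)
    for (i in seq_along(radii)) {
      d <- divide_equal_flux(dens$values[i, ], theta, n_tracks)
      bsup[i, ] <- d$superior
      binf[i, ] <- d$inferior
    }
    sup_models <- fit_hemisphere_boundaries(bsup, radii, r0, c_bounds)
    inf_models <- fit_hemisphere_boundaries(binf, radii, r0, c_bounds)
    boundaries <- c(list(arcuate_model(0, 0, 1, r0, zero_b = TRUE)),
                    sup_models,
                    list(arcuate_model(180, 0, 1, r0, zero_b = TRUE)),
                    inf_models)
    traj <- trajectory_map(boundaries, radii)
    beta_now <- skew_beta_matrix(traj, radii, theta)
    # under-relaxation once the update stalls: near-radial borders can flip
    # between two near-equal exponent fits, sustaining a small limit cycle;
    # averaging with the previous skew field breaks the cycle without
    # moving the fixed point
    if (relax < 1) beta_now <- relax * beta_now + (1 - relax) * beta_prev
    if (it >= 2L) {
      dmax <- max(abs(beta_now - beta_prev))
      delta_history <- c(delta_history, dmax)
      if (dmax < tol_deg) {
        converged <- TRUE
        beta_prev <- beta_now
        cosb <- cos(deg2rad(beta_now))
        break
      }
      nh <- length(delta_history)
      if (nh >= 4 && it - last_damp >= 3 && relax > 0.05 &&
          delta_history[nh] > 0.5 * delta_history[nh - 3]) {
        relax <- relax / 2   # stalled or cycling: damp the updates
        last_damp <- it
      }
      if (nh >= 4 && all(diff(delta_history[(nh - 3):nh]) > 0)) {
        flagged <- TRUE   # divergence guard: delta increasing 3 times in a row
        warning("trajectory tracing diverging; returning best iterate")
        break
      }
    }
    beta_prev <- beta_now
    cosb <- cos(deg2rad(beta_now))
  }
  if (!converged && !flagged) {
    flagged <- TRUE
    warning("trajectory tracing did not converge within ", max_iter,
            " iterations")
  }
  # track monotonicity check on the converged map
  ba <- boundary_angles(traj, radii)
  if (any(apply(ba, 2, function(x) any(diff(x) <= 0)))) {
    flagged <- TRUE
    warning("fitted track borders cross at one or more radii")
  }
  list(trajectory = traj,
       cos_beta = polar_annulus_map(cosb, radii = radii,
                                    quantity = "cos_beta"),
       beta = beta_prev,
       iterations = it,
       converged = converged,
       delta_history = delta_history,
       flagged = flagged)
}
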